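# Shared fixture builders: everything is generated in code, no stored data.

# One activity record with clean defaults; override any field.
record <- function(target_id = "T1", family = "gpcr", compound_id = "C1",
                   smiles = "S1", relation = "=", pchembl = 7.0,
                   doc_id = "d1", src_id = 1L, duplicate_flag = FALSE,
                   data_validity_comment = NA_character_,
                   activity_comment = NA_character_, ...) {
  data.frame(target_id = target_id, family = family,
             compound_id = compound_id, smiles = smiles,
             relation = relation, pchembl = pchembl, doc_id = doc_id,
             src_id = src_id, duplicate_flag = duplicate_flag,
             data_validity_comment = data_validity_comment,
             activity_comment = activity_comment, ...,
             stringsAsFactors = FALSE)
}

records <- function(...) do.call(rbind, list(...))

# A block of clean records for one target: n_active actives and
# n_inactive inactives on the right side of the family threshold, spread
# over n_docs documents.
target_block <- function(target_id = "T1", family = "gpcr",
                         n_active = 45L, n_inactive = 35L, n_docs = 3L,
                         margin = 0.6) {
  thr <- idg_threshold(family)
  n <- n_active + n_inactive
  record(
    target_id = target_id, family = family,
    compound_id = sprintf("%s_C%03d", target_id, seq_len(n)),
    smiles = sprintf("%s_S%03d", target_id, seq_len(n)),
    pchembl = c(thr + margin + seq_len(n_active) / 100,
                thr - margin - seq_len(n_inactive) / 100),
    doc_id = rep_len(paste0(target_id, "_d", seq_len(n_docs)), n))
}

# Small labelled feature set with tunable separability, built on the
# package generator.
make_xy <- function(n = 120, separability = 0.9, seed = 1,
                    active_fraction = 0.5, noise = 0, bits = 256,
                    informative = 32) {
  g <- generate_features(n, active_fraction, separability, informative,
                         seed = seed, n_bits = bits, label_noise = noise)
  rownames(g$x) <- sprintf("C%04d", seq_len(n))
  g
}

# Random prediction-set outcome tables for metric identity properties.
random_outcomes <- function(n, seed) {
  set.seed(seed)
  list(sets = sample(c("active", "inactive", "both", "empty"), n, TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)),
       labels = sample(c("active", "inactive"), n, TRUE))
}
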