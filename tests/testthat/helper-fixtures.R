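# Small in-code fixtures shared across test files.

# Minimal two-dataset count table with controls, built by hand.
make_test_table <- function() {
  m <- matrix(c(
    # B1  B2  E1  E2  E3
      40,  40,  10,  5,  0,   # ctrl-dominant contaminant
      5,   6, 100, 80, 90,    # true resident, trace in controls
      0,   0,  50, 60, 70,    # true resident, absent from controls
      1,   0,   0,  0,  0     # singleton (total 1)
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("ASV_A", "ASV_B", "ASV_C", "ASV_D"),
                  c("B1", "B2", "E1", "E2", "E3")))
  as_feature_table(m)
}

make_test_metadata <- function() {
  data.frame(
    sample_id = c("B1", "B2", "E1", "E2", "E3"),
    role = c("control", "control", rep("experimental", 3)),
    dataset = "ds1", tissue = "gut", stringsAsFactors = FALSE)
}

# Count table engineered so pooled percentages match the published Aedes
# block (counts = percent x 100 over one control and one gut column), with
# the remaining read mass spread over background features below every
# threshold (0.67% each in the control).
make_aedes_count_table <- function() {
  feats <- c("Enterobacter_1", "Enterobacter_2", "Serratia_1", "Cutibacterium_1",
             paste0("bg", 1:50), "gut_only")
  ctrl <- c(4006, 1964, 569, 111, rep(67, 50), 0)
  gut <- c(2589, 1305, 1016, 0, rep(101, 50), 40)
  stopifnot(sum(ctrl) == 10000, sum(gut) == 10000)
  m <- cbind(B1 = ctrl, G1 = gut)
  rownames(m) <- feats
  as_feature_table(m)
}

make_aedes_metadata <- function() {
  data.frame(sample_id = c("B1", "G1"),
             role = c("control", "experimental"),
             dataset = "Aedes", tissue = "gut", stringsAsFactors = FALSE)
}

random_table <- function(n_feat = 25, n_samp = 6, lambda = 8) {
  m <- matrix(stats::rpois(n_feat * n_samp, lambda), n_feat, n_samp,
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  m
}
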