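# Fickett (1982) TESTCODE lookup tables, transcribed from the original
# publication (Nucleic Acids Research 10:5303-5318): for each base, the
# probability that a sequence is coding given its positional-asymmetry
# parameter (max/(min+1) of the base's counts in the three codon positions)
# or its content fraction, plus the published parameter weights. Parameter
# thresholds are in decreasing order; a value v maps to the first bin whose
# threshold is <= v.

.fickett_position_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

.fickett_content_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

# first bin whose threshold is <= value (thresholds strictly decreasing)
.fickett_bin <- function(value, para) {
  which(value >= para)[1L]
}
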