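#' Amino-acid z-descriptor scales
#'
#' Five physicochemical descriptor variables per amino acid: z1
#' (hydrophobicity), z2 (steric bulk), z3 (polarity), z4 and z5 (electronic
#' effects), from the extended principal-property z-scales of Sandberg et
#' al. (1998, J Med Chem 41:2481-2491). Used to encode antigen-binding-site
#' residues before supertype clustering. Supply an alternative table of the
#' same shape to [encode_pss()] to use different scales.
#'
#' @format A tibble with 20 rows and columns `aa`, `z1`..`z5`.
#' @export
z_descriptors <- tibble::tibble(
  aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  z1 = c(0.24, 3.52, 3.05, 3.98, 0.84, 1.75, 3.11, 2.05, 2.47, -3.89,
         -4.28, 2.29, -2.85, -4.22, -1.66, 2.39, 0.75, -4.36, -2.54, -2.59),
  z2 = c(-2.32, 2.50, 1.62, 0.93, -1.67, 0.50, 0.26, -4.06, 1.95, -1.73,
         -1.30, 0.89, -0.22, 1.94, 0.27, -1.07, -2.18, 3.94, 2.44, -2.64),
  z3 = c(0.60, -3.50, 1.04, 1.93, 3.71, -1.44, -0.11, 0.36, 0.26, -1.71,
         -1.49, -2.49, 0.47, 1.06, 1.84, 1.15, -1.12, 0.59, 0.43, -1.54),
  z4 = c(-0.14, 1.99, -1.15, -2.46, 0.18, -1.34, -3.04, -0.82, 3.90, -0.84,
         -0.72, 1.49, 1.94, 0.54, 0.70, -1.39, -1.46, 3.44, 0.04, -0.85),
  z5 = c(1.30, -0.17, 1.61, 0.75, -2.65, 0.66, -0.25, -0.38, 0.09, 0.26,
         0.84, 0.31, -0.98, -0.62, 2.00, 0.67, -0.40, -1.59, -1.47, -0.02)
)
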