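#' Path to the bundled Wisconsin diagnostic table
#'
#' The package ships the public-domain Breast Cancer Wisconsin (Diagnostic)
#' mean-feature table (569 records: diagnosis label, mean radius and nine
#' further mean cytology features) as a plain CSV, so every real-data
#' analysis in the package runs without a download.
#'
#' @return File path of the bundled CSV.
#' @export
wdbc_path <- function() {
  system.file("extdata", "wdbc_diagnostic.csv", package = "betaridge",
              mustWork = TRUE)
}

#' Reference moments of the diagnostic-table features
#'
#' Published per-feature means and standard deviations of the nine
#' continuous mean cytology features, used by [gen_wdbc_like()] to give the
#' emulated table the correct marginal location and spread.
#'
#' @return A data.frame with columns `variable`, `mean`, `sd`.
#' @export
wdbc_moments <- function() {
  data.frame(
    variable = c("texture_mean", "perimeter_mean", "area_mean",
                 "smoothness_mean", "compactness_mean", "concavity_mean",
                 "concave_points_mean", "symmetry_mean",
                 "fractal_dimension_mean"),
    mean = c(19.2896, 91.9690, 654.8891, 0.0964, 0.1043, 0.0888,
             0.0489, 0.1812, 0.0628),
    sd = c(4.30104, 24.29898, 351.91413, 0.01406, 0.05281, 0.07972,
           0.03880, 0.02741, 0.00706))
}

#' Reference correlation structure of the diagnostic table
#'
#' Published pairwise correlations among the diagnosis indicator and the
#' nine continuous features (printed to three decimals, so the assembled
#' matrix can be marginally non-positive-definite; [gen_wdbc_like()] repairs
#' it by eigenvalue clipping).
#'
#' @return A symmetric 10 x 10 correlation matrix with unit diagonal.
#' @export
wdbc_correlations <- function() {
  vars <- c("diagnosis", wdbc_moments()$variable)
  R <- matrix(0, 10, 10, dimnames = list(vars, vars))
  lower <- list(
    c(0.415),                                                  # texture
    c(0.743, 0.330),                                           # perimeter
    c(0.709, 0.321, 0.987),                                    # area
    c(0.359, -0.023, 0.207, 0.177),                            # smoothness
    c(0.597, 0.237, 0.557, 0.499, 0.659),                      # compactness
    c(0.696, 0.302, 0.716, 0.686, 0.522, 0.883),               # concavity
    c(0.777, 0.293, 0.851, 0.823, 0.554, 0.831, 0.921),        # concave pts
    c(0.330, 0.071, 0.183, 0.151, 0.558, 0.603, 0.501, 0.462), # symmetry
    c(-0.013, -0.076, -0.261, -0.283, 0.585, 0.565, 0.337,
      0.167, 0.480))                                           # fractal dim
  for (i in 2:10) R[i, seq_len(i - 1)] <- lower[[i - 1]]
  R <- R + t(R)
  diag(R) <- 1
  R
}
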