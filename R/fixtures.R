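rsmopt_extdata <- function(file) {
  system.file("extdata", file, package = "rsmopt", mustWork = TRUE)
}

#' The 27-run coffee-husk extraction dataset
#'
#' The four-factor, three-level Box-Behnken experiment on aqueous phenolic
#' extraction from milled coffee husk: 24 edge runs and 3 centre replicates
#' over temperature (30-100 degC), time (5-90 min), acidity (0-2 % citric
#' acid) and solid-to-liquid ratio (0.02-0.05 g/mL), with seven responses in
#' mg per g dry husk: total phenolic compounds (TPC), flavonoids (TF),
#' flavanols (TFL), proanthocyanidins (PAC), phenolic acids (TPA),
#' ortho-diphenols (TOD) and ABTS antioxidant capacity (AC). Tabulated
#' response means are used for modelling; the replicate standard deviations
#' travel along in `*_sd` columns for reference.
#'
#' @return A `design_table` with 27 runs, run order as tabulated.
#' @examples
#' des <- coffee_husk_design()
#' des$TPC[20]  # 4.88
#' @export
coffee_husk_design <- function() {
  read_design(rsmopt_extdata("coffee_husk_bbd.csv"), husk_factors())
}

#' Validation and extraction-comparison table
#'
#' Model-predicted (RSM and ANN, with their published CV%) and experimental
#' response values at the optimal (100 degC, 90 min, 0% acid, 0.02 g/mL)
#' and suboptimal (5 min) extraction conditions, for milled and raw husk,
#' alongside the conventional organic-solvent extraction results (free,
#' bound and total phenolic fractions). All in mg per g dry husk.
#'
#' Note: the tabulated TPA value 23.64 for the raw husk at the suboptimal
#' condition is inconsistent with its neighbours and is carried as printed.
#'
#' @return Data frame, one row per response.
#' @export
validation_table <- function() {
  utils::read.csv(rsmopt_extdata("validation_panel.csv"),
                  check.names = FALSE)
}

#' UPLC-ESI-MS/MS phenolic compound profile
#'
#' Concentrations (ug per g dry husk) of 18 phenolic compounds in the
#' aqueous extracts (optimal/suboptimal conditions, milled/raw husk) and in
#' the organic-solvent free and bound fractions, with retention times and
#' MS transitions. Empty cells are concentrations below detection.
#'
#' @return Data frame, one row per compound.
#' @examples
#' cp <- compound_profile()
#' cp$free[cp$compound == "Chlorogenic acid"]  # 1428.40
#' @export
compound_profile <- function() {
  utils::read.csv(rsmopt_extdata("compound_profile.csv"),
                  check.names = FALSE)
}

#' Seven-sample chemometric panel
#'
#' Assembles the panel used for correlation, PCA, PLS and clustering
#' analyses: the four aqueous extracts (optimal/suboptimal x milled/raw),
#' the organic free and bound fractions, and the organic total, as rows;
#' the seven in vitro responses, the 18 individual compounds and the summed
#' compound concentration (`total_uplc`) as columns.
#'
#' @param missing How to treat below-detection compound entries: `"zero"`
#'   (default; absence treated as a true zero concentration) or `"na"`
#'   (excluded pairwise / imputed downstream).
#' @param include_sums Append the `total_uplc` column (default `TRUE`).
#' @return Data frame with 7 rows (`Op1_Milled`, `Op1_Raw`, `Op2_Milled`,
#'   `Op2_Raw`, `Free`, `Bound`, `Total`).
#' @examples
#' panel <- extract_panel()
#' pearson_matrix(panel)$r["Chlorogenic acid", "TPC"]
#' @export
extract_panel <- function(missing = c("zero", "na"), include_sums = TRUE) {
  missing <- match.arg(missing)
  val <- validation_table()
  cp <- compound_profile()
  samples <- c("Op1_Milled", "Op1_Raw", "Op2_Milled", "Op2_Raw",
               "Free", "Bound", "Total")
  vit_cols <- c("exp_opt_milled", "exp_opt_raw", "exp_sub_milled",
                "exp_sub_raw", "free", "bound", "total")
  cmp_cols <- c("opt_milled", "opt_raw", "sub_milled", "sub_raw",
                "free", "bound", "total")
  vit <- t(as.matrix(val[vit_cols]))
  colnames(vit) <- val$response
  cmp <- t(as.matrix(cp[cmp_cols]))
  colnames(cmp) <- cp$compound
  if (missing == "zero") cmp[is.na(cmp)] <- 0
  out <- data.frame(vit, cmp, check.names = FALSE)
  rownames(out) <- samples
  if (include_sums)
    out$total_uplc <- rowSums(cmp, na.rm = TRUE)
  out
}
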