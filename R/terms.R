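#' Term sets for second-order polynomial models
#'
#' Model terms are written in the coded factor symbols: `"X1"` (linear),
#' `"X1^2"` (quadratic), `"X1:X3"` (two-factor interaction, symbols in
#' design order). `full_quadratic()` returns the complete second-order set
#' for a factor list: k linear + k quadratic + k(k-1)/2 interaction terms.
#'
#' @param factors List of [factor_spec()] objects.
#' @return Character vector of term labels.
#' @examples
#' length(full_quadratic(husk_factors()))  # 14
#' @export
full_quadratic <- function(factors) {
  syms <- unname(vapply(check_factor_list(factors), `[[`, "", "symbol"))
  k <- length(syms)
  inter <- if (k >= 2) {
    idx <- utils::combn(k, 2)
    paste0(syms[idx[1, ]], ":", syms[idx[2, ]])
  } else character()
  c(syms, paste0(syms, "^2"), inter)
}

term_parents <- function(term) {
  if (grepl("\\^2$", term)) sub("\\^2$", "", term)
  else if (grepl(":", term, fixed = TRUE)) strsplit(term, ":", fixed = TRUE)[[1]]
  else character()
}

#' Close a term set under model hierarchy
#'
#' Adds the parent linear terms of every quadratic and interaction term, so
#' the returned set describes a hierarchical (well-formed) polynomial.
#'
#' @param terms Character vector of term labels.
#' @param symbols Factor symbols, used to return terms in canonical order
#'   (linear, quadratic, interactions).
#' @return Character vector of term labels.
#' @export
hierarchy_closure <- function(terms, symbols) {
  symbols <- unname(symbols)
  need <- unique(c(terms, unlist(lapply(terms, term_parents))))
  canonical <- c(symbols, paste0(symbols, "^2"),
                 if (length(symbols) >= 2) {
                   idx <- utils::combn(length(symbols), 2)
                   paste0(symbols[idx[1, ]], ":", symbols[idx[2, ]])
                 })
  canonical[canonical %in% need]
}

#' Build the model matrix for a term set
#'
#' Columns are ordered intercept, then the terms as given; interaction
#' columns are elementwise products of the coded parent columns, quadratic
#' columns elementwise squares.
#'
#' @param design A `design_table`, or a numeric matrix/data frame of coded
#'   values with factor symbols as column names.
#' @param terms Character vector of term labels.
#' @return Numeric matrix with `length(terms) + 1` columns.
#' @export
build_design_matrix <- function(design, terms) {
  coded <- if (inherits(design, "design_table")) coded_matrix(design)
           else as.matrix(design)
  cols <- lapply(terms, function(tm) {
    if (grepl("\\^2$", tm)) {
      s <- sub("\\^2$", "", tm)
      if (!s %in% colnames(coded)) stop("missing factor column: ", s,
                                        call. = FALSE)
      coded[, s]^2
    } else if (grepl(":", tm, fixed = TRUE)) {
      ss <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(ss %in% colnames(coded)))
        stop("missing factor column in term ", tm, call. = FALSE)
      coded[, ss[1]] * coded[, ss[2]]
    } else {
      if (!tm %in% colnames(coded)) stop("missing factor column: ", tm,
                                         call. = FALSE)
      coded[, tm]
    }
  })
  X <- cbind(1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  X
}
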