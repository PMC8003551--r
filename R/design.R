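#' Generate a Box-Behnken design
#'
#' Builds the three-level Box-Behnken design for `k >= 3` factors: for every
#' unordered pair of factors the four sign combinations (-,-), (+,-), (-,+),
#' (+,+) are applied to that pair while all remaining factors are held at
#' their centre, followed by `n_center` centre replicates. For four factors
#' this gives the classic 24 edge runs; with three centre points, 27 runs.
#' Run order is deterministic: factor pairs in lexicographic order, the four
#' sign combinations in the order above, centre points last.
#'
#' @param factors List of [factor_spec()] objects (at least 3).
#' @param n_center Number of centre replicates (default 3).
#' @return A `design_table`: a data frame with a `run` column, one natural
#'   column per factor (named by factor symbol with suffix none) and the
#'   factor list stored as an attribute. Coded values are recovered with
#'   [coded_matrix()].
#' @examples
#' des <- bbd_design(husk_factors())
#' nrow(des)  # 27
#' @export
bbd_design <- function(factors, n_center = 3) {
  factors <- check_factor_list(factors)
  k <- length(factors)
  if (k < 3) stop("unsupported design: Box-Behnken needs at least 3 factors",
                  call. = FALSE)
  if (n_center < 1) stop("'n_center' must be >= 1", call. = FALSE)
  pairs <- utils::combn(k, 2)
  signs <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1))
  coded <- matrix(0, nrow = 4 * ncol(pairs) + n_center, ncol = k)
  row <- 1L
  for (p in seq_len(ncol(pairs))) {
    for (s in seq_len(4)) {
      coded[row, pairs[, p]] <- signs[s, ]
      row <- row + 1L
    }
  }
  colnames(coded) <- vapply(factors, `[[`, "", "symbol")
  natural <- coded
  for (j in seq_len(k)) natural[, j] <- decode_value(coded[, j], factors[[j]])
  out <- data.frame(run = seq_len(nrow(coded)), natural, check.names = FALSE)
  names(out)[-1] <- names(factors)
  as_design_table(out, factors)
}

#' Assemble a design table from natural-unit data
#'
#' Wraps a data frame of natural factor settings (and optionally response
#' columns) as a `design_table`, attaching the factor specifications that
#' define the coded transform. Any column that is neither `run` nor a factor
#' is treated as a response.
#'
#' @param data Data frame with one column per factor, named as in
#'   `names(factors)`, plus optional `run` and response columns.
#' @param factors List of [factor_spec()] objects.
#' @return A `design_table` data frame.
#' @export
as_design_table <- function(data, factors) {
  factors <- check_factor_list(factors)
  missing <- setdiff(names(factors), names(data))
  if (length(missing))
    stop("design is missing factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(data$run)) data$run <- seq_len(nrow(data))
  responses <- setdiff(names(data), c("run", names(factors)))
  responses <- responses[!grepl("_sd$", responses)]
  nonnum <- responses[!vapply(data[responses], is.numeric, TRUE)]
  if (length(nonnum))
    stop("non-numeric response column(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  structure(data, factors = factors, responses = responses,
            class = c("design_table", "data.frame"))
}

#' Coded factor matrix of a design
#'
#' @param design A `design_table`.
#' @return Numeric matrix (runs x factors) of coded values, columns named by
#'   factor symbol.
#' @export
coded_matrix <- function(design) {
  factors <- design_factors(design)
  out <- vapply(seq_along(factors),
                function(j) code_value(design[[names(factors)[j]]],
                                       factors[[j]]),
                numeric(nrow(design)))
  colnames(out) <- vapply(factors, `[[`, "", "symbol")
  out
}

#' Accessors for design tables
#'
#' @param design A `design_table`.
#' @return `design_factors()` returns the list of [factor_spec()] objects;
#'   `design_responses()` the response column names.
#' @export
design_factors <- function(design) {
  factors <- attr(design, "factors")
  if (is.null(factors)) stop("not a design_table: no factor attribute",
                             call. = FALSE)
  factors
}

#' @rdname design_factors
#' @export
design_responses <- function(design) attr(design, "responses")

#' @export
print.design_table <- function(x, ...) {
  factors <- design_factors(x)
  cat(sprintf("Design table: %d runs, %d factors (%s)\n", nrow(x),
              length(factors),
              paste(vapply(factors, `[[`, "", "symbol"), collapse = ", ")))
  resp <- design_responses(x)
  if (length(resp))
    cat("Responses:", paste(resp, collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a design table from CSV
#'
#' @param path CSV file with one column per factor (natural units) plus
#'   optional `run` and response columns.
#' @param factors List of [factor_spec()] objects.
#' @return A `design_table`.
#' @export
read_design <- function(path, factors) {
  as_design_table(utils::read.csv(path, check.names = FALSE), factors)
}

#' Write a design table to CSV
#'
#' Writes the natural columns, coded columns (suffix `_coded`) and responses.
#'
#' @param design A `design_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  out <- as.data.frame(design)
  cm <- coded_matrix(design)
  colnames(cm) <- paste0(colnames(cm), "_coded")
  utils::write.csv(cbind(out, cm), path, row.names = FALSE)
  invisible(path)
}
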