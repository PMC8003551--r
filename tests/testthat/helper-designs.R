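# small factor sets and designs shared across tests

toy_factors <- function(k = 3) {
  fs <- lapply(seq_len(k), function(i)
    factor_spec(paste0("f", i), paste0("X", i), 0, 2, "u"))
  names(fs) <- paste0("f", seq_len(k))
  fs
}

# tiny fully-known regression problem for OLS oracle checks
tiny_design <- function(seed = 42) {
  set.seed(seed)
  fs <- toy_factors(3)
  des <- bbd_design(fs, n_center = 2)[1:8, ]
  des <- as_design_table(as.data.frame(des), fs)
  out <- as.data.frame(des)
  out$y <- round(stats::rnorm(nrow(out), 5, 1), 3)
  as_design_table(out, fs)
}

husk_full_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- coffee_husk_design()
      resp <- design_responses(des)
      cache <<- lapply(stats::setNames(resp, resp),
                       function(r) rsm_quad(des, r))
    }
    cache
  }
})
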