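#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom purrr map map_dbl map2 imap
#' @importFrom stats rnorm runif cor sd var lm coef optim pchisq pt qnorm
#'   p.adjust t.test ks.test rbinom quantile median complete.cases setNames
#'   rchisq predict
#' @importFrom utils head write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sfgc <- function(msg, class = "sfgc_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_sfgc(msg)
  invisible(TRUE)
}

# symmetric within tolerance
check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  assert_that(is.matrix(m) && nrow(m) == ncol(m), paste(what, "must be square"))
  assert_that(max(abs(m - t(m))) <= tol, paste(what, "must be symmetric"))
  invisible(TRUE)
}

# derive a stream-specific child seed from a parent seed; keeps every stage
# independently reproducible while all flowing from one global seed
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * (31L^(seq_along(utf8ToInt(as.character(stream))) %% 7L)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
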