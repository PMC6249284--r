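#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed; each stage draws
#' from its own stream so that adding a stage never perturbs the others.
#' Derived seeds stay below 2^31 - 1.
#'
#' @param root integer root seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  # cheap string hash (polynomial rolling, modulo a Mersenne prime)
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(root) * 2654435 + h) %% 2147483647)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must contain probabilities in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# deterministic manifest hash of an R object (text-serialized)
object_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
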