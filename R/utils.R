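# Internal helpers: classed conditions, seed derivation, deterministic I/O.

vb_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "vepbench_error", "error"),
                      call = call))
}

vb_check <- function(ok, msg, class = "vepbench_validation_error") {
  if (!isTRUE(ok)) vb_error(msg, class, call = sys.call(-1))
  invisible(TRUE)
}

vb_log <- function(...) {
  if (isTRUE(getOption("vepbench.verbose", TRUE))) {
    message("[vepbench] ", ...)
  }
  invisible(NULL)
}

# Deterministic 31-polynomial string hash modulo a Mersenne prime.
# Used to derive independent, order-insensitive RNG streams per label;
# all arithmetic stays below 2^53 so doubles are exact.
hash_string <- function(s) {
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  h
}

#' Derive a child seed from a root seed and a label
#'
#' Combos and pipeline stages each draw from their own RNG stream derived
#' deterministically from the run's single root seed, so results do not
#' depend on evaluation order.
#'
#' @param seed integer root seed.
#' @param label character label of the stream (e.g. a combo id).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  vb_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
           "seed must be a single finite number")
  h <- hash_string(paste0(label, "#", seed %% 2147483647))
  as.integer((h %% 2147483645) + 1)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the global
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    }, add = TRUE)
  }
  set.seed(seed)
  expr
}

# Fixed-format numeric rendering so that repeated runs write byte-identical
# files. 15 significant digits round-trips doubles for our value ranges.
vb_format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.15g", v)
  }, character(1))
  out
}

vb_write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- vb_format_num(df2[[j]])
    }
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

vb_read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
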