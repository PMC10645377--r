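`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

warn_ <- function(...) warning(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_fraction <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Derive a per-stream seed from a global seed
#'
#' Each stochastic generator draws from its own substream so that adding or
#' reordering generators does not perturb the streams of the others.
#'
#' @param seed integer global seed.
#' @param stream character stream label.
#' @return an integer seed below 2^31.
#' @keywords internal
stream_seed <- function(seed, stream) {
  offsets <- c(expression = 101L, dose_response = 211L, cohort = 307L,
               ihc = 401L, pipeline = 503L)
  if (!stream %in% names(offsets)) stop_("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 2654435L + offsets[[stream]]) %% 2147483647)
}

# write via temp file in the same directory, then rename, so a failed writer
# never leaves a partial output behind
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop_("could not move temporary file onto ", path)
  invisible(path)
}
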