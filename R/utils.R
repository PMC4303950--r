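# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a deterministic child seed from a root seed and a string label
#'
#' Stochastic operations that loop over pathways draw one child seed per
#' (root seed, pathway id, draw label) so results are stable under reordering
#' of the input collection. The derivation is a plain polynomial string hash
#' folded with the root seed, kept strictly below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param label character scalar (e.g. a pathway id plus draw index).
#' @return a single integer seed.
#' @keywords internal
child_seed <- function(seed, label) {
  m <- 2147483629 # largest prime < 2^31 used as modulus
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 31 + cc) %% m
  as.integer((as.numeric(seed) %% m + h + 1) %% m)
}

# split lines on tabs keeping trailing empty fields (base strsplit drops them)
.split_tsv <- function(lines) {
  parts <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

.read_text_lines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

.is_comment_or_blank <- function(lines) {
  startsWith(lines, "#") | !nzchar(trimws(lines))
}
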