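#' @keywords internal
"_PACKAGE"

# Run an expression with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Mixes a global integer seed with a stage label so that pipeline stages can
#' be re-run independently while remaining reproducible from one master seed.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 2654435761) %% 2147483647)
}

# Sniff the field delimiter (tab or comma) from the first line of a file.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com && n_tab > 0L) "\t"
  else if (n_com > 0L) ","
  else if (grepl("[ ]", first)) "" # whitespace (1KGP panel files)
  else "\t"
}

read_delim_sniffed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_delim(path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
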