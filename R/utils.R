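#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over a character string, done in doubles to stay portable
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  h
}

#' Derive a stage seed from the global seed
#'
#' Stages of the pipeline draw their randomness from seeds derived by
#' stable hashing of the stage name, so each stage is independently
#' reproducible from the single global seed.
#'
#' @param global_seed integer global seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(global_seed, stage) {
  as.integer((abs(global_seed) * 7919 + fnv1a32(stage) %% 2^28) %% (2^31 - 1))
}

# short hex digest of an R object (FNV over its deparsed form); used to
# stamp output files with the configuration they came from
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = " ")
  sprintf("%08x", fnv1a32(txt))
}

# write a data.frame as TSV with a provenance header comment
write_tsv_stamped <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
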