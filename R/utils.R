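#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spawn reproducible child seeds from a master seed
#'
#' Deterministically derives `n` integer seeds from one master seed, so that
#' independent simulation streams (one per study, one for the planted
#' signature) can be re-created individually.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, all in `[1, 2^31 - 2]`.
#' @keywords internal
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# md5 of the JSON serialization of a (config-like) list; used in output
# headers and run manifests so outputs can be traced to their configuration.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

pkg_version_string <- function() {
  as.character(utils::packageVersion("rygbsig"))
}

# Write a result data.frame as TSV with "#"-prefixed header comment lines
# carrying the package version and, when supplied, a config hash.
write_result_tsv <- function(df, path, comments = character()) {
  lines <- c(sprintf("# rygbsig %s", pkg_version_string()), comments)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(ifelse(startsWith(lines, "#"), "", "# "), lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
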