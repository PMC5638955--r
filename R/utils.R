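#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# internal: stop with a consistent error class so the CLI can trap validation
# failures before any output is written
.fail <- function(..., class = "ptascreen_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) .fail(...)
}

# clip numeric array/matrix into [lo, hi]
.clip <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# OLS slope of y on x with intercept; returns c(slope, r_squared)
# kept minimal because it runs once per moving-window position
.ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(c(slope = NA_real_, r_squared = NA_real_))
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else (sxy^2) / (sxx * syy)
  c(slope = slope, r_squared = r2)
}

# md5 of a canonical YAML rendering of a config list (provenance header)
.config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

# provenance header lines for output files; the hash covers analysis
# parameters only, not input/output locations, so reruns of the same
# analysis hash identically wherever they write
.provenance_header <- function(subcommand, config, rng_seed = NA) {
  drop <- c("out", "out_prefix", "tracks", "frames", "od", "gff", "vcf",
            "fasta", "rates", "config", "help")
  config <- config[setdiff(names(config), drop)]
  c(
    paste0("# ptascreen ", as.character(utils::packageVersion("ptascreen"))),
    paste0("# subcommand: ", subcommand),
    paste0("# config_hash: ", .config_hash(config)),
    paste0("# rng_seed: ", rng_seed)
  )
}

# write a data.frame as CSV with '#' provenance header lines
.write_csv_prov <- function(df, path, header_lines) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by ptascreen (skipping provenance header lines)
#'
#' @param path file path
#' @return data.frame
#' @export
read_ptascreen_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
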