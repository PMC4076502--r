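#' Read a wide counts file of 2x3 genotype tables
#'
#' One SNP per row. The header must name the arm and genotype of every count
#' column: `snp, case_AA, case_Aa, case_aa, ctrl_AA, ctrl_Aa, ctrl_aa`.
#' Genotype columns follow the fixed (AA, Aa, aa) order with `a` the
#' minor/risk allele; the reader never guesses allele orientation -- use
#' `flip = TRUE` to reverse a file coded the other way round.
#'
#' @param path Path to the delimited file.
#' @param dialect `"wide_tsv"` (tab-separated, default) or `"csv"`.
#' @param flip Reverse the genotype column order (aa, Aa, AA -> AA, Aa, aa)
#'   in both arms.
#' @return A tibble with columns `snp` and the six counts; zero rows (with
#'   a warning) if the file has a header but no data.
#' @export
read_counts <- function(path, dialect = c("wide_tsv", "csv"), flip = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path,
    header = TRUE, sep = sep, colClasses = "character",
    check.names = FALSE, strip.white = TRUE
  )
  missing <- setdiff(c("snp", counts_cols), names(df))
  if (length(missing)) {
    stop(sprintf(
      "%s: malformed header, missing column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning(path, ": no data rows", call. = FALSE)
    return(tibble::as_tibble(df[c("snp", counts_cols)]))
  }
  for (col in counts_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad)) {
      stop(sprintf(
        "%s: line %d, column %s: '%s' is not a non-negative integer",
        path, bad[1] + 1L, col, df[[col]][bad[1]]
      ), call. = FALSE)
    }
    df[[col]] <- as.integer(round(v))
  }
  out <- tibble::as_tibble(df[c("snp", counts_cols)])
  if (flip) {
    out <- out[c(
      "snp", "case_aa", "case_Aa", "case_AA",
      "ctrl_aa", "ctrl_Aa", "ctrl_AA"
    )]
    names(out) <- c("snp", counts_cols)
  }
  for (i in seq_len(nrow(out))) {
    arm_x <- sum(out[i, c("case_AA", "case_Aa", "case_aa")])
    arm_y <- sum(out[i, c("ctrl_AA", "ctrl_Aa", "ctrl_aa")])
    if (arm_x == 0 || arm_y == 0) {
      stop(sprintf(
        "%s: line %d (%s): empty %s arm",
        path, i + 1L, out$snp[i], if (arm_x == 0) "case" else "control"
      ), call. = FALSE)
    }
  }
  out
}

#' Read per-individual records and collapse to genotype counts
#'
#' Expects a tab-separated file with header columns `sample`, `phenotype`
#' (0 = control, 1 = case), `genotype` (0/1/2 = count of the minor allele
#' `a`, or the missing token). Individuals with a missing genotype are
#' dropped with a warning reporting how many. Optionally a `snp` column
#' splits records across SNPs.
#'
#' @param path Path to the file.
#' @param missing Token marking a missing genotype (default `"NA"`).
#' @return A counts tibble in the same layout as [read_counts()].
#' @export
read_individuals <- function(path, missing = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", colClasses = "character",
    check.names = FALSE, strip.white = TRUE, na.strings = character(0)
  )
  need <- c("sample", "phenotype", "genotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf(
      "%s: malformed header, missing column(s): %s",
      path, paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  if (!"snp" %in% names(df)) df$snp <- "snp1"
  bad <- which(!df$phenotype %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d: phenotype '%s' is not 0/1",
      path, bad[1] + 1L, df$phenotype[bad[1]]
    ), call. = FALSE)
  }
  bad <- which(!df$genotype %in% c("0", "1", "2", missing))
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d: genotype '%s' is not 0/1/2 or '%s'",
      path, bad[1] + 1L, df$genotype[bad[1]], missing
    ), call. = FALSE)
  }
  dropped <- sum(df$genotype == missing)
  if (dropped) {
    warning(sprintf(
      "%s: dropped %d individual(s) with missing genotype",
      path, dropped
    ), call. = FALSE)
  }
  df <- df[df$genotype != missing, , drop = FALSE]
  if (nrow(df) == 0) stop(path, ": no usable records", call. = FALSE)
  df$genotype <- as.integer(df$genotype)
  df$phenotype <- as.integer(df$phenotype)
  purrr::map_dfr(split(df, df$snp), function(d) {
    tally <- function(ph, g) sum(d$phenotype == ph & d$genotype == g)
    tibble::tibble(
      snp = d$snp[1],
      case_AA = tally(1L, 0L), case_Aa = tally(1L, 1L),
      case_aa = tally(1L, 2L),
      ctrl_AA = tally(0L, 0L), ctrl_Aa = tally(0L, 1L),
      ctrl_aa = tally(0L, 2L)
    )
  })
}

#' Write a results table as TSV or JSON
#'
#' Numeric values are rendered at 17 significant digits in both formats, so
#' the two outputs carry identical values at full double precision.
#'
#' @param df A data frame of results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- as.data.frame(df)
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        out[[col]] <- format(out[[col]], digits = 17, trim = TRUE)
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file carries the [simulation_config()] fields by name; unspecified
#' fields take the constructor defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(simulation_config))
  extra <- setdiff(names(vals), allowed)
  if (length(extra)) {
    stop(
      "unknown simulation config field(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(simulation_config, vals)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed, package version and R version of an
#' experiment run as JSON.
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  manifest <- list(
    config = unclass(config),
    package = "exacttrend",
    package_version = as.character(utils::packageVersion("exacttrend")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
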