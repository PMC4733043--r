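#' Read and write model rates as a flat config file
#'
#' The config format is one \code{key = value} pair per line with keys
#' \code{k_de_novo}, \code{k_fission}, \code{gamma}, \code{k_fusion}; lines
#' starting with \code{#} are comments. Values round-trip at full floating
#' precision.
#'
#' @param rates A \code{\link{model_rates}} object.
#' @param path File path.
#' @return \code{read_rates_config} returns a \code{model_rates};
#'   \code{write_rates_config} returns \code{path} invisibly.
#' @export
write_rates_config <- function(rates, path) {
  rates <- as_model_rates(rates)
  lines <- sprintf("%s = %s", names(rates),
                   vapply(rates, format_full, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rates_config
#' @export
read_rates_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop(sprintf("malformed config line: '%s'", lines[bad][1]), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  known <- c("k_de_novo", "k_fission", "gamma", "k_fusion")
  if (!all(keys %in% known))
    stop(sprintf("unknown config key: '%s'", setdiff(keys, known)[1]),
         call. = FALSE)
  args <- as.list(structure(vals, names = keys))
  do.call(model_rates, args)
}

# full-precision decimal rendering (17 significant digits round-trips doubles)
format_full <- function(x) format(x, digits = 17, scientific = FALSE)

#' Serialise model rates to and from JSON
#'
#' @param rates A \code{\link{model_rates}} object.
#' @param json A JSON string as produced by \code{rates_to_json}.
#' @return \code{rates_to_json} returns a JSON string; \code{rates_from_json}
#'   returns a \code{model_rates}. The round trip is lossless.
#' @export
rates_to_json <- function(rates) {
  rates <- as_model_rates(rates)
  # I(17): 17 *significant* digits, enough to round-trip any double
  jsonlite::toJSON(unclass(rates), auto_unbox = TRUE, digits = I(17))
}

#' @rdname rates_to_json
#' @export
rates_from_json <- function(json) {
  do.call(model_rates, jsonlite::fromJSON(json))
}

#' Write and read a count distribution as TSV
#'
#' Two tab-separated columns (\code{n}, \code{probability}) preceded by
#' \code{#}-comment header lines carrying the model rates, the tail bound
#' and the package version. \code{read_distribution} restores the
#' distribution, including its rates, so the round trip is faithful.
#'
#' @param dist A \code{"count_distribution"}.
#' @param path File path.
#' @return \code{write_distribution} returns \code{path} invisibly;
#'   \code{read_distribution} returns a \code{"count_distribution"}.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "count_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(dist$rates)) {
    r <- dist$rates
    writeLines(sprintf("# rates: k_de_novo=%s k_fission=%s gamma=%s k_fusion=%s",
                       format_full(r$k_de_novo), format_full(r$k_fission),
                       format_full(r$gamma), format_full(r$k_fusion)), con)
  }
  writeLines(sprintf("# tail_bound: %s", format_full(dist$tail_bound)), con)
  writeLines(sprintf("# orgdist_version: %s", as.character(packageVersion("orgdist"))), con)
  writeLines("n\tprobability", con)
  writeLines(sprintf("%d\t%s", dist$n,
                     vapply(dist$probabilities, format_full, character(1))),
             con)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  headers <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  rates <- NULL
  rl <- grep("^# rates:", headers, value = TRUE)
  if (length(rl) == 1L) {
    kv <- regmatches(rl, gregexpr("[a-z_]+=[-0-9.eE+]+", rl))[[1]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    args <- as.list(as.numeric(vapply(parts, `[`, character(1), 2L)))
    names(args) <- vapply(parts, `[`, character(1), 1L)
    rates <- do.call(model_rates, args)
  }
  tb <- 0
  tl <- grep("^# tail_bound:", headers, value = TRUE)
  if (length(tl) == 1L)
    tb <- as.numeric(sub("^# tail_bound:\\s*", "", tl))
  dat <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                    sep = "\t")
  count_distribution(dat$n, dat$probability, tail_bound = tb, rates = rates)
}

#' Write a trajectory or ensemble snapshot as TSV
#'
#' Trajectories are written as two columns (\code{time}, \code{count});
#' snapshots as (\code{n}, \code{cells}). Both carry the run configuration
#' in \code{#}-comment header lines.
#'
#' @param x A \code{"trajectory"} or \code{"ensemble_snapshot"}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_simulation_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- x$config
  r <- cfg$rates
  writeLines(sprintf("# rates: k_de_novo=%s k_fission=%s gamma=%s k_fusion=%s",
                     format_full(r$k_de_novo), format_full(r$k_fission),
                     format_full(r$gamma), format_full(r$k_fusion)), con)
  writeLines(sprintf("# n0=%d scheme=%s dt=%s seed=%s", cfg$n0, cfg$scheme,
                     format_full(cfg$dt), format_full(cfg$seed)), con)
  if (inherits(x, "trajectory")) {
    writeLines(sprintf("# t_end=%s", format_full(x$t_end)), con)
    writeLines("time\tcount", con)
    writeLines(sprintf("%s\t%d",
                       vapply(x$time, format_full, character(1)), x$count),
               con)
  } else if (inherits(x, "ensemble_snapshot")) {
    writeLines(sprintf("# tau=%s cells=%d", format_full(x$tau), x$n_cells),
               con)
    writeLines("n\tcells", con)
    writeLines(sprintf("%d\t%d", x$n, x$cells), con)
  } else {
    stop("'x' must be a trajectory or ensemble_snapshot", call. = FALSE)
  }
  invisible(path)
}

#' Read an observed count histogram from a plain-text file
#'
#' Auto-detects the two accepted layouts: a single column of per-cell
#' integer counts (one cell per line), or two whitespace/tab-separated
#' columns (count, number of cells at that count), with or without a header
#' line. Lines starting with \code{#} are ignored.
#'
#' @param path File path.
#' @return A numeric vector of per-cell counts.
#' @export
read_count_histogram <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no data lines in histogram file", call. = FALSE)
  fields <- strsplit(lines, "[ \t,]+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% c(1L, 2L))
    stop("histogram file must have one column (counts per cell) or two columns (count, cells)",
         call. = FALSE)
  # tolerate a single header line of non-numeric labels
  first_numeric <- !anyNA(suppressWarnings(as.numeric(fields[[1]])))
  if (!first_numeric) {
    fields <- fields[-1]
    if (length(fields) == 0L)
      stop("no data lines in histogram file", call. = FALSE)
  }
  mat <- suppressWarnings(vapply(fields, as.numeric, numeric(ncols)))
  if (anyNA(mat))
    stop("non-numeric entry in histogram file", call. = FALSE)
  if (ncols == 1L) as.numeric(mat)
  else rep(mat[1, ], times = mat[2, ])
}

#' Write a Fano-mean curve as TSV
#'
#' Three tab-separated columns (\code{sweep_value}, \code{mean},
#' \code{fano}) with the family tag in a \code{#}-comment header.
#'
#' @param curve A \code{"fano_mean_curve"} from \code{\link{fano_mean_curve}}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_fano_mean_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fano_mean_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# family: %s", attr(curve, "family")), con)
  writeLines("sweep_value\tmean\tfano", con)
  writeLines(sprintf("%s\t%s\t%s",
                     vapply(curve$sweep_value, format_full, character(1)),
                     vapply(curve$mean, format_full, character(1)),
                     vapply(curve$fano, format_full, character(1))), con)
  invisible(path)
}
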