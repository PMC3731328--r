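# File I/O for reference tables, fixture generation, and result export.
#
# Table format: plain text, two columns `q,f` (comma or whitespace
# delimited), `.` decimal marks, optional `#`-prefixed comment lines before
# the data; a comment of the form `# Z = 14` names the element.

#' Read a two-column form-factor table from disk
#'
#' @param path Path to a text file with columns `q` (1/Angstrom, strictly
#'   ascending) and `f` (dimensionless, non-negative).  Lines starting with
#'   `#` are kept as metadata; a comment `# Z = <n>` sets the element.
#' @param Z Atomic number override; defaults to the value found in the
#'   comments, else `NA`.
#' @return An [ff_table()] with the comment lines in `$comments`.
#' @export
read_ff_table <- function(path, Z = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("no such file: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  comments <- lines[is_comment]
  data_lines <- lines[!is_comment & !is_blank]
  # tolerate a non-numeric header row
  first_fields <- strsplit(trimws(data_lines[1]), "[,[:space:]]+")[[1]]
  if (length(data_lines) > 0 &&
      any(is.na(suppressWarnings(as.numeric(first_fields))))) {
    data_lines <- data_lines[-1]
  }
  if (length(data_lines) < 2) {
    stop("a form-factor table needs at least 2 data rows", call. = FALSE)
  }
  line_no <- which(!is_comment & !is_blank)
  line_no <- line_no[(length(line_no) - length(data_lines) + 1):length(line_no)]
  parsed <- lapply(data_lines, function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
  })
  bad <- which(vapply(parsed, function(p) length(p) < 2 || any(is.na(p[1:2])),
                      logical(1)))
  if (length(bad) > 0) {
    stop(sprintf("line %d of %s is not a `q,f` pair", line_no[bad[1]], path),
         call. = FALSE)
  }
  q <- vapply(parsed, `[`, numeric(1), 1L)
  f <- vapply(parsed, `[`, numeric(1), 2L)
  if (any(diff(q) <= 0)) {
    i <- which(diff(q) <= 0)[1] + 1L
    stop(sprintf("q values not strictly ascending at line %d of %s",
                 line_no[i], path), call. = FALSE)
  }
  if (any(f < 0)) {
    i <- which(f < 0)[1]
    stop(sprintf("negative f value at line %d of %s", line_no[i], path),
         call. = FALSE)
  }
  if (is.null(Z)) {
    m <- regmatches(comments, regexpr("Z\\s*=\\s*[0-9]+", comments))
    Z <- if (length(m) > 0) {
      as.integer(sub("Z\\s*=\\s*", "", m[[1]]))
    } else {
      NA_integer_
    }
  }
  ff_table(Z, q, f, comments = comments)
}

#' Generate a sparse or dense form-factor fixture table
#'
#' Evaluates one of the packaged closed forms on a uniform momentum-transfer
#' grid, emulating the sparse tables a table-driven Monte Carlo code
#' carries.  The default grid (85 points on \[0, 16\] 1/Angstrom)
#' reproduces the sparse-table scenario covering all scattering angles for
#' photon energies up to about 15.8 keV.
#'
#' @param Z Atomic number; 1..30 for `source = "eq6"`, exactly 1 for
#'   `source = "eq5"`.
#' @param n_points Number of grid points (default 85).
#' @param q_range Two-element range of q in 1/Angstrom (default `c(0, 16)`).
#' @param source `"eq6"` (the empirical function with the packaged
#'   parameters) or `"eq5"` (the hydrogen closed form).
#' @param path Optional file path; when given, the table is also written to
#'   disk in the two-column format of [read_ff_table()].
#' @return The generated [ff_table()], invisibly when `path` is given.
#' @examples
#' tab <- generate_fixture(1, source = "eq5")
#' length(tab$q)
#' @export
generate_fixture <- function(Z, n_points = 85, q_range = c(0, 16),
                             source = c("eq6", "eq5"), path = NULL) {
  source <- match.arg(source)
  q <- seq(q_range[1], q_range[2], length.out = n_points)
  f <- if (source == "eq5") {
    if (Z != 1) {
      stop("the hydrogen closed form (`eq5`) is only defined for Z = 1",
           call. = FALSE)
    }
    hydrogen_ff(q)
  } else {
    suppressWarnings(empirical_ff(q, get_params(Z)))
  }
  tab <- ff_table(Z, q, f,
                  comments = sprintf("# Z = %d (%s, %d points on [%g, %g])",
                                     as.integer(Z), source, n_points,
                                     q_range[1], q_range[2]))
  if (!is.null(path)) {
    writeLines(c(tab$comments, "q,f",
                 sprintf("%.17g,%.17g", tab$q, tab$f)), path)
    return(invisible(tab))
  }
  tab
}

.provenance_lines <- function(extra = character()) {
  c(sprintf("# ffmc %s", as.character(utils::packageVersion("ffmc"))),
    extra)
}

#' Write a result object to CSV or JSON
#'
#' Exports the package's result types with stable column order, floating
#' point at 17 significant digits, and a provenance header (package version
#' plus configuration echo) as `#` comments (CSV) or a `meta` field (JSON).
#'
#' @param object A `deviation_summary`, `angular_pdf`, `sample_batch`,
#'   `ff_params` or `mode_comparison`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- .as_result_df(object)
  meta <- attr(df, "meta")
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenance_lines(meta), con)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(meta = list(
      package = paste0("ffmc ", as.character(utils::packageVersion("ffmc"))),
      note = sub("^# ", "", paste(meta, collapse = "; "))),
      data = df)
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

# Flattens a result object to a data frame plus provenance metadata.
.as_result_df <- function(object) {
  if (inherits(object, "deviation_summary")) {
    df <- data.frame(delta_max = object$delta_max,
                     delta_mean = object$delta_mean,
                     delta_std = object$delta_std,
                     n_points = object$n_points)
    attr(df, "meta") <- "# deviation summary (percent)"
    df
  } else if (inherits(object, "angular_pdf")) {
    e <- object$bin_edges
    df <- data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
                     density = object$density)
    attr(df, "meta") <- sprintf(
      "# angular pdf (%s): Z = %d, E = %g keV, convention = %s",
      object$source, object$config$Z, object$config$energy_kev,
      object$config$kin$convention)
    df
  } else if (inherits(object, "sample_batch")) {
    df <- data.frame(theta_rad = object$angles)
    attr(df, "meta") <- sprintf(
      "# sampled angles: Z = %d, E = %g keV, mode = %s, seed = %d, convention = %s",
      object$config$Z, object$config$energy_kev, object$config$mode,
      object$config$seed, object$config$kin$convention)
    df
  } else if (inherits(object, "ff_params")) {
    df <- data.frame(Z = object$Z, r = object$r, a1 = object$a1,
                     b1 = object$b1, a2 = object$a2, b2 = object$b2,
                     a3 = object$a3, b3 = object$b3,
                     delta_max = object$delta_max,
                     delta_mean = object$delta_mean,
                     delta_std = object$delta_std)
    attr(df, "meta") <- "# empirical form-factor parameters"
    df
  } else if (inherits(object, "mode_comparison")) {
    df <- object$per_seed
    attr(df, "meta") <- sprintf(
      "# LIT vs analytic reduced chi-square: Z = %d, E = %g keV, n = %d; medians %.6g / %.6g; sign p = %.6g",
      object$Z, object$energy_kev, object$n_photons,
      object$median_analytic, object$median_table, object$p_sign)
    df
  } else {
    stop("unsupported result type for write_results()", call. = FALSE)
  }
}
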