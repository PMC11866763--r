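# Delimited-text I/O. Every output file starts with '#' metadata lines
# sufficient to reproduce it; mode tables round-trip bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a mode table
#'
#' Format: '#' metadata/comment lines, a header `mode,freq_cm1,g,f_au`, one
#' comma-separated row per mode. Reduced-unit sets record their unit system
#' in the metadata. Values are written with full precision so a write/read
#' cycle is bit-exact.
#'
#' @param modes an [discrete_modes()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modes <- function(modes, path) {
  if (!inherits(modes, "ndc_modes")) ndc_stop("modes must be an ndc_modes object")
  labels <- if (is.null(modes$labels))
    sprintf("m%03d", seq_along(modes$omega)) else modes$labels
  lines <- c(
    sprintf("# ndcrate mode table (%d modes)", length(modes$omega)),
    sprintf("# units: %s", modes$units),
    "mode,freq_cm1,g,f_au",
    sprintf("%s,%s,%s,%s", labels, fmt_num(modes$omega),
            fmt_num(modes$g), fmt_num(modes$f)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a mode table
#'
#' Accepts comma- or whitespace-delimited rows, ignores blank lines and `#`
#' comments, and validates every row (errors cite the offending line number).
#'
#' @param path input file path.
#' @return an [discrete_modes()] object.
#' @export
read_modes <- function(path) {
  if (!file.exists(path)) ndc_stop("mode table not found: ", path)
  raw <- readLines(path, warn = FALSE)
  units <- if (any(grepl("^#\\s*units:\\s*reduced", raw))) "reduced" else "cm1"
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  rows <- trimws(raw[keep])
  if (length(rows) == 0L) return(discrete_modes(numeric(0), units = units))
  split_row <- function(r) {
    parts <- strsplit(r, "[,[:space:]]+")[[1]]
    parts[nzchar(parts)]
  }
  first <- split_row(rows[1])
  has_header <- any(grepl("^(mode|freq)", first, ignore.case = TRUE))
  if (has_header) { rows <- rows[-1]; lineno <- lineno[-1] }
  if (length(rows) == 0L) return(discrete_modes(numeric(0), units = units))
  parse_row <- function(i) {
    parts <- split_row(rows[i])
    if (length(parts) != 4L)
      ndc_stop("parse error at line ", lineno[i], " of ", path,
               ": expected 4 fields (mode,freq,g,f), found ", length(parts))
    vals <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(vals)))
      ndc_stop("parse error at line ", lineno[i], " of ", path,
               ": non-numeric field in '", rows[i], "'")
    if (vals[1] <= 0)
      ndc_stop("validation error at line ", lineno[i], " of ", path,
               ": mode frequency must be positive (got ", vals[1], ")")
    list(label = parts[1], vals = vals)
  }
  parsed <- lapply(seq_along(rows), parse_row)
  discrete_modes(
    omega = vapply(parsed, function(p) p$vals[1], numeric(1)),
    g = vapply(parsed, function(p) p$vals[2], numeric(1)),
    f = vapply(parsed, function(p) p$vals[3], numeric(1)),
    labels = vapply(parsed, function(p) p$label, character(1)),
    units = units)
}

meta_header <- function(..., units) {
  c(sprintf("# ndcrate %s", utils::packageDescription("ndcrate")$Version),
    sprintf("# units: %s", units),
    ...)
}

#' Write spectral-density tables
#'
#' Continuous densities on the given frequency grid as
#' `omega_cm1,J,J_D,J_F`; analytic point masses are recorded as metadata
#' lines (they are never discretized onto the grid).
#'
#' @param triple an `ndc_triple`.
#' @param omega frequency grid (unit system of the triple).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(triple, omega, path) {
  ev <- eval_triple(triple, omega)
  dl <- ev$deltas
  lines <- c(
    meta_header(sprintf("# kind: %s", triple$kind), units = triple$units),
    if (nrow(dl)) sprintf("# delta: omega=%s wJ=%s wJD=%s wJF=%s",
                          fmt_num(dl$omega), fmt_num(dl$wJ),
                          fmt_num(dl$wJD), fmt_num(dl$wJF)),
    "omega_cm1,J,J_D,J_F",
    sprintf("%s,%s,%s,%s", fmt_num(omega), fmt_num(ev$J),
            fmt_num(ev$J_D), fmt_num(ev$J_F)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a correlation-function table
#'
#' Columns `t_ps,Re_g,Im_g,Re_F,Im_F,Re_D,Im_D` (t in ps, F in ps^-1, D in
#' ps^-2; reduced units when the set is reduced), preceded by a metadata
#' header.
#'
#' @param corr an `ndc_corr` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corr <- function(corr, path) {
  if (!inherits(corr, "ndc_corr")) ndc_stop("corr must be an ndc_corr object")
  df <- as.data.frame(corr)
  temp <- if (corr$units == "reduced")
    sprintf("theta = %g", 1 / corr$thermo$temperature)
  else sprintf("T = %g K", corr$thermo$temperature)
  lines <- c(
    meta_header(sprintf("# method: %s", corr$method),
                sprintf("# thermo: %s", temp),
                sprintf("# lambda_over_hbar: %s", fmt_num(corr$lambda)),
                units = corr$units),
    "t_ps,Re_g,Im_g,Re_F,Im_F,Re_D,Im_D",
    do.call(sprintf, c(list("%s,%s,%s,%s,%s,%s,%s"),
                       lapply(df, fmt_num))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a rate-scan table
#'
#' Columns `gap,k,k_condon,ln_k_scaled,converged` plus a metadata header.
#'
#' @param scan an `ndc_scan` data frame from [gap_scan()].
#' @param path output file path.
#' @param description optional free-text description recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, description = NULL) {
  if (!inherits(scan, "ndc_scan")) ndc_stop("scan must come from gap_scan()")
  lines <- c(
    meta_header(if (!is.null(description)) paste("#", description),
                units = attr(scan, "units")),
    "gap,k,k_condon,ln_k_scaled,converged",
    sprintf("%s,%s,%s,%s,%s", fmt_num(scan$gap), fmt_num(scan$k),
            fmt_num(scan$k_condon), fmt_num(scan$ln_k_scaled),
            scan$converged))
  writeLines(lines, path)
  invisible(path)
}
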