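#' Write / read an umbrella-window trajectory file
#'
#' Plain text, one floating-point z value (Angstrom) per line. On reading,
#' a leading sample-index column (as some MD colvar writers emit) is
#' auto-detected and dropped.
#'
#' @param series An `umbrella_series` (or numeric vector).
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a numeric vector of z samples.
#' @export
write_trajectory <- function(series, path) {
  samples <- if (inherits(series, "umbrella_series")) series$samples
             else as.numeric(series)
  writeLines(sprintf("%.10g", samples), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "numeric")
  if (ncol(tab) >= 2L) tab[[2]] else tab[[1]]
}

#' Write / read an umbrella metadata file
#'
#' Whitespace-delimited lines "trajectory-path  center(Angstrom)
#' force-constant(kcal mol^-1 A^-2)" with `#` comments — the de facto
#' metadata dialect of 1-D WHAM tools. Paths are stored relative to the
#' metadata file's directory.
#'
#' @param layout A [make_window_layout()] with an additional `path` column.
#' @param path Metadata file path.
#' @param bias_half Bias convention flag recorded as a header comment.
#' @return `write_umbrella_metadata` returns `path` invisibly;
#'   `read_umbrella_metadata` returns a data frame with columns `path`
#'   (absolute), `center`, `k` and attribute `bias_half`.
#' @export
write_umbrella_metadata <- function(layout, path, bias_half = TRUE) {
  stopifnot(is.data.frame(layout), all(c("path", "center", "k") %in%
                                         names(layout)))
  lines <- c(sprintf("# umbrella metadata: trajectory  center(A)  k(kcal/mol/A^2)"),
             sprintf("# bias_half %s", if (bias_half) "true" else "false"),
             sprintf("%s  %.6f  %.6f", layout$path, layout$center, layout$k))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_umbrella_metadata
#' @export
read_umbrella_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  raw <- readLines(path)
  bias_half <- TRUE
  bh <- grep("^#\\s*bias_half\\b", raw, value = TRUE)
  if (length(bh) > 0L)
    bias_half <- grepl("true", bh[1], ignore.case = TRUE)
  raw <- trimws(sub("#.*$", "", raw))
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "\\s+")
  if (any(lengths(parts) < 3L))
    stop("malformed metadata line(s): expected 'path center k'")
  df <- data.frame(
    path = vapply(parts, `[[`, "", 1L),
    center = as.numeric(vapply(parts, `[[`, "", 2L)),
    k = as.numeric(vapply(parts, `[[`, "", 3L)))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(normalizePath(path)), df$path[rel])
  if (anyDuplicated(df$center)) stop("duplicate window centers in metadata")
  attr(df, "bias_half") <- bias_half
  df
}

#' Load umbrella series from a metadata file
#'
#' @param metadata Path to a metadata file, or the data frame from
#'   [read_umbrella_metadata()].
#' @return List of `umbrella_series` in metadata order.
#' @export
read_umbrella_series <- function(metadata) {
  meta <- if (is.character(metadata)) read_umbrella_metadata(metadata)
          else metadata
  bias_half <- isTRUE(attr(meta, "bias_half"))
  lapply(seq_len(nrow(meta)), function(i) {
    if (!file.exists(meta$path[i]))
      stop(sprintf("metadata line %d: trajectory file not found: %s",
                   i, meta$path[i]))
    structure(list(samples = read_trajectory(meta$path[i]),
                   sample_interval = 1L, seed = NA_integer_,
                   window = list(center = meta$center[i], k = meta$k[i],
                                 bias_half = bias_half)),
              class = "umbrella_series")
  })
}

#' Write / read a PMF profile as TSV
#'
#' Tab-separated columns `z`, `w`, `stderr`, `n` with `#`-prefixed header
#' lines recording temperature, bin width, offset convention and (when
#' anchored) the bulk range, so the producing stage can be re-run from the
#' file alone.
#'
#' @param pmf A [pmf_profile()].
#' @param path File path.
#' @return `write_pmf` returns `path` invisibly; `read_pmf` returns the
#'   `pmf_profile`.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  hdr <- c(sprintf("# PMF profile (pmfbind %s)",
                   as.character(utils::packageVersion("pmfbind"))),
           sprintf("# temperature_K %.6f", attr(pmf, "temperature")),
           sprintf("# bin_width_A %.6g", attr(pmf, "bin_width")),
           sprintf("# offset %s", attr(pmf, "offset")))
  if (!is.null(attr(pmf, "bulk_range")))
    hdr <- c(hdr, sprintf("# bulk_range_A %.6f %.6f",
                          attr(pmf, "bulk_range")[1],
                          attr(pmf, "bulk_range")[2]))
  hdr <- c(hdr, "# z_A\tw_kcal_mol\tstderr_kcal_mol\tn")
  body <- sprintf("%.6f\t%s\t%s\t%s", pmf$z,
                  ifelse(is.na(pmf$w), "NA", sprintf("%.10g", pmf$w)),
                  ifelse(is.na(pmf$stderr), "NA",
                         sprintf("%.10g", pmf$stderr)),
                  ifelse(is.na(pmf$n), "NA", sprintf("%d", pmf$n)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  if (!file.exists(path)) stop("PMF file not found: ", path)
  raw <- readLines(path)
  hdr <- raw[startsWith(raw, "#")]
  get_hdr <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(sub(paste0("^#\\s*", key), "", ln[1])), "\\s+")[[1]]
  }
  tab <- utils::read.table(text = raw[!startsWith(raw, "#")], sep = "\t",
                           header = FALSE, na.strings = "NA")
  names(tab) <- c("z", "w", "stderr", "n")[seq_len(ncol(tab))]
  temperature <- as.numeric(get_hdr("temperature_K") %||% "310.15")
  offset <- get_hdr("offset") %||% "raw"
  bulk <- get_hdr("bulk_range_A")
  pmf_profile(z = tab$z, w = tab$w,
              stderr = if ("stderr" %in% names(tab)) tab$stderr else NA_real_,
              n = if ("n" %in% names(tab)) tab$n else NA_integer_,
              temperature = temperature, offset = offset,
              bin_width = as.numeric(get_hdr("bin_width_A") %||% NA),
              bulk_range = if (is.null(bulk)) NULL else as.numeric(bulk))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a binding report
#'
#' TSV key-value block echoing all parameters, site bounds and provenance,
#' followed by a human-readable summary. The one-dimensional caveat is
#' stated in every report: the K_D is an effective value estimated from a
#' one-dimensional approximation for the process.
#'
#' @param result A [binding_result()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_binding_report <- function(result, path) {
  stopifnot(inherits(result, "binding_result"))
  p <- result$params
  kv <- c(
    sprintf("kd_M\t%.10g", result$kd),
    sprintf("dg_kcal_mol\t%.10g", result$dg),
    sprintf("stderr_dg_kcal_mol\t%s",
            if (is.finite(result$stderr_dg))
              sprintf("%.10g", result$stderr_dg) else "NA"),
    sprintf("site_lo_A\t%s\nsite_hi_A\t%s",
            if (is.null(result$site_bounds)) "NA"
            else sprintf("%.6f", result$site_bounds[1]),
            if (is.null(result$site_bounds)) "NA"
            else sprintf("%.6f", result$site_bounds[2])),
    sprintf("temperature_K\t%.6f", p$temperature),
    sprintf("kB_kcal_mol_K\t%.10g", p$kB),
    sprintf("N_A_per_mol\t%.10g", p$N_A),
    sprintf("cylinder_radius_A\t%.6f", p$cylinder_radius),
    sprintf("standard_conc_M\t%.6f", p$standard_conc),
    sprintf("provenance_hash\t%s",
            result$provenance$pmf_hash %||% "NA"))
  summary_lines <- c(
    "# ---- summary ----",
    sprintf("# K_D = %s; Delta G = %.2f kcal/mol%s", format_kd(result$kd),
            result$dg,
            if (is.finite(result$stderr_dg))
              sprintf(" +/- %.2f", result$stderr_dg) else ""),
    "# Effective value estimated from one-dimensional approximation for the",
    sprintf("# process, under a flat-bottom cylindrical restraint of radius %g Angstrom.",
            p$cylinder_radius))
  writeLines(c("# binding report (pmfbind)", kv, summary_lines), path)
  invisible(path)
}

# ---- run configuration --------------------------------------------------

config_schema <- function() {
  list(
    potential = list(type = "character", default = "open-like"),
    z_min = list(type = "numeric", default = -49.5),
    z_max = list(type = "numeric", default = -7.5),
    spacing = list(type = "numeric", default = 0.5),
    force_constant = list(type = "numeric", default = 10),
    bias_half = list(type = "logical", default = TRUE),
    n_steps = list(type = "numeric", default = 220000),
    dt = list(type = "numeric", default = 0.02),
    diffusion = list(type = "numeric", default = 1),
    scheme = list(type = "character", default = "metropolis"),
    temperature = list(type = "numeric", default = 310.15),
    bin_width = list(type = "numeric", default = 0.1),
    burn_in_fraction = list(type = "numeric", default = 2 / 22),
    tolerance = list(type = "numeric", default = 1e-7),
    max_iter = list(type = "numeric", default = 1e5),
    cylinder_radius = list(type = "numeric", default = 10),
    standard_conc = list(type = "numeric", default = 1),
    bulk_width = list(type = "numeric", default = 5),
    site_lo = list(type = "numeric", default = NA_real_),
    site_hi = list(type = "numeric", default = NA_real_),
    n_boot = list(type = "numeric", default = 0),
    seed = list(type = "numeric", default = NA_real_),
    out_dir = list(type = "character", default = "."))
}

#' Read and validate a run configuration
#'
#' Flat `key = value` text (one pair per line, `#` comments). Unknown keys
#' are rejected by name; missing keys take documented defaults (see
#' `pmfbind::config_schema()` source for the full schema). A seed is
#' mandatory for pipeline runs.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  schema <- config_schema()
  cfg <- lapply(schema, `[[`, "default")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- readLines(path)
    raw <- trimws(sub("#.*$", "", raw))
    raw <- raw[nzchar(raw)]
    for (line in raw) {
      if (!grepl("=", line, fixed = TRUE))
        stop("malformed config line (expected 'key = value'): ", line)
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      if (!key %in% names(schema))
        stop("unknown config key: '", key, "'")
      cfg[[key]] <- val
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(schema)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- overrides[[key]]
  }
  for (key in names(cfg)) {
    cfg[[key]] <- switch(schema[[key]]$type,
      numeric = as.numeric(cfg[[key]]),
      logical = if (is.logical(cfg[[key]])) cfg[[key]]
                else tolower(as.character(cfg[[key]])) %in%
                       c("true", "t", "yes", "1"),
      character = as.character(cfg[[key]]))
    if (schema[[key]]$type == "numeric" && !is.na(cfg[[key]]) &&
        !is.finite(cfg[[key]]))
      stop("config key '", key, "' is not numeric")
  }
  structure(cfg, class = "run_config")
}
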