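## Report writers and small unit conversions.
##
## TSV output uses a fixed 6-significant-digit float format so repeated
## runs are byte-identical; JSON summaries keep full precision and carry a
## configuration hash for provenance.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "infeasible", formatC(x, format = "g", digits = 6))
  sub("^-(0(\\.0*)?)$", "\\1", out)  # normalize "-0"
}

#' Cell dry weight from optical density
#'
#' Applies the experimentally determined conversion
#' `CDW (g/L) = 0.27 x OD600` for C. glutamicum cultures.
#'
#' @param od600 Non-negative optical density at 600 nm.
#' @return Cell dry weight in g/L.
#' @export
cdw_from_od <- function(od600) {
  if (any(is.na(od600)) || any(od600 < 0))
    stop("od600 must be non-negative")
  0.27 * od600
}

#' Write a flux state (or FVA brackets) as TSV
#'
#' @param state A `flux_state`, or a data frame with a `reaction` column
#'   (e.g. [fva()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(state, path) {
  df <- if (inherits(state, "flux_state"))
    data.frame(reaction = names(state$fluxes), flux = unname(state$fluxes))
  else state
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flux TSV back into a named vector or data frame
#'
#' @param path A file written by [write_flux_tsv()].
#' @return Named numeric vector when the file has columns
#'   `reaction`/`flux`; otherwise the parsed data frame.
#' @export
read_flux_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (j in seq_along(df))
    if (is.character(df[[j]]) && names(df)[j] != "reaction" &&
        names(df)[j] != "direction" && names(df)[j] != "label" &&
        names(df)[j] != "status") {
      v <- suppressWarnings(as.numeric(ifelse(df[[j]] == "infeasible",
                                              NA, df[[j]])))
      if (!all(is.na(v) & df[[j]] != "infeasible")) df[[j]] <- v
    }
  if (identical(names(df), c("reaction", "flux")))
    stats::setNames(df$flux, df$reaction)
  else df
}

#' Serialize a scan result to long-format TSV
#'
#' One row per reaction x multiplier with the uptake-normalized flux
#' change and the direction class of the comparison against the wild-type
#' reference (heatmap-ready: `up`/`down`/`reversed`/`unchanged` as a
#' categorical column). Infeasible cells are flagged, not blank.
#'
#' @param scan A `scan_result` from [acn_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  rows <- list()
  wt <- scan$reference_state
  for (i in seq_along(scan$spec$multipliers)) {
    k <- scan$spec$multipliers[i]
    st <- scan$states[[i]]
    if (is.null(st)) {
      rows[[i]] <- data.frame(reaction = rownames(scan$delta_matrix),
                              multiplier = k, flux = NA_real_,
                              delta_normalized = NA_real_,
                              direction = "infeasible")
    } else {
      dm <- delta_map(wt, st, reaction_by_role_or_first_uptake(scan))
      rows[[i]] <- data.frame(reaction = dm$reaction, multiplier = k,
                              flux = dm$alt_flux,
                              delta_normalized = dm$delta_normalized,
                              direction = dm$direction)
    }
  }
  df <- do.call(rbind, rows)
  df$multiplier <- fmt_num(df$multiplier)
  df$flux <- fmt_num(df$flux)
  df$delta_normalized <- fmt_num(df$delta_normalized)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

reaction_by_role_or_first_uptake <- function(scan) {
  ## the scan recorded |uptake|; recover the uptake id from the reference
  ## state by matching the normalization base
  fl <- scan$reference_state$fluxes
  hit <- names(fl)[abs(abs(fl) - scan$uptake) < 1e-9 &
                     startsWith(names(fl), "EX_")]
  if (length(hit)) hit[1] else names(fl)[1]
}

#' Serialize a robustness surface to long-format TSV
#'
#' One row per (growth, flux) cell; infeasible cells carry the flag
#' `infeasible` in the product column.
#'
#' @param surface A `robustness_surface` from [double_robustness()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surface, path) {
  stopifnot(inherits(surface, "robustness_surface"))
  df <- expand.grid(growth = surface$growth_values,
                    flux = surface$flux_values,
                    KEEP.OUT.ATTRS = FALSE)
  df$product <- as.vector(surface$objective_matrix)
  df <- df[order(df$growth, df$flux), ]
  df$growth <- fmt_num(df$growth)
  df$flux <- fmt_num(df$flux)
  df$product <- fmt_num(df$product)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result bundle with provenance
#'
#' Writes each named result to `<outdir>/<name>.tsv` (choosing the writer
#' by class) plus a `summary.json` holding scalar metadata and a hash of
#' the configuration for provenance. File naming is deterministic and
#' repeated runs with equal inputs are byte-identical.
#'
#' @param results Named list: `flux_state`, `scan_result`,
#'   `robustness_surface` or data-frame entries.
#' @param outdir Output directory (created if needed).
#' @param config Optional list echoed (hashed) into the summary.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(results, outdir, config = list()) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("unwritable directory: ", outdir)
  paths <- character(0)
  summary <- list(config_hash = config_hash(config))
  for (nm in names(results)) {
    x <- results[[nm]]
    p <- file.path(outdir, paste0(nm, ".tsv"))
    if (inherits(x, "flux_state")) {
      write_flux_tsv(x, p)
      summary[[nm]] <- list(status = x$status,
                            objective_value = x$objective_value)
    } else if (inherits(x, "scan_result")) {
      write_scan_tsv(x, p)
      summary[[nm]] <- list(best_multiplier = x$best_multiplier,
                            product_trace = x$product_trace)
    } else if (inherits(x, "robustness_surface")) {
      write_surface_tsv(x, p)
      summary[[nm]] <- list(max_cell = x$max_cell)
    } else if (is.data.frame(x)) {
      write_flux_tsv(x, p)
    } else stop("cannot serialize result '", nm, "'")
    paths <- c(paths, p)
  }
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}

## order-insensitive FNV-1a hash of the deparsed config (no external deps)
config_hash <- function(config) {
  if (length(config)) config <- config[order(names(config))]
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), ch)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}
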