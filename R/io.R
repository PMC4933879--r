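# CSV I/O with a commented metadata header ("# key: value" lines), so a
# file round-trips the generator truth and seed alongside the data

write_meta_csv <- function(df, path, meta) {
  header <- purrr::imap_chr(meta, function(v, k) {
    sprintf("# %s: %s", k, paste(format(v, digits = 15), collapse = " "))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_meta_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      vals <- strsplit(trimws(m[3]), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(vals))
      meta[[trimws(m[2])]] <- if (anyNA(num)) vals else num
    }
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  list(data = as_tibble(df), meta = meta)
}

#' Write / read a titration dataset as CSV
#'
#' Data columns `concentration_M`, `signal`; the probe concentration, label
#' and (for synthetic data) truth and seed travel in `# key: value` comment
#' lines.
#'
#' @param data Titration tibble (columns `conc`, `dfluo`) with the
#'   attributes attached by [sim_titration()].
#' @param path File path.
#' @param label Free-text label stored in the header.
#' @return The path (writer) or a tibble with attributes restored (reader).
#' @export
write_titration_csv <- function(data, path, label = "titration") {
  meta <- list(label = label,
               probe_conc_M = attr(data, "probe_conc"))
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    meta$true_kd_M <- truth$kd
    meta$true_fmax <- truth$fmax
  }
  if (!is.null(attr(data, "seed"))) meta$seed <- attr(data, "seed")
  write_meta_csv(tibble(concentration_M = data$conc, signal = data$dfluo),
                 path, meta)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  r <- read_meta_csv(path)
  out <- tibble(conc = r$data$concentration_M, dfluo = r$data$signal)
  attr(out, "probe_conc") <- r$meta$probe_conc_M
  if (!is.null(r$meta$true_kd_M)) {
    attr(out, "truth") <- list(kd = r$meta$true_kd_M,
                               fmax = r$meta$true_fmax)
  }
  attr(out, "seed") <- r$meta$seed
  attr(out, "label") <- r$meta$label
  out
}

#' Write / read a kinetic trace as CSV
#'
#' Data columns `time_s`, `signal`; ligand concentration and metadata in the
#' commented header.
#'
#' @param trace Trace tibble (columns `time`, `signal`).
#' @param path File path.
#' @param ligand_conc Optional ligand concentration, mol/L.
#' @param label Free-text label.
#' @return The path (writer) or an attributed tibble (reader).
#' @export
write_trace_csv <- function(trace, path, ligand_conc = NULL,
                            label = "trace") {
  meta <- list(label = label)
  if (!is.null(ligand_conc)) meta$ligand_conc_M <- ligand_conc
  truth <- attr(trace, "truth")
  if (!is.null(truth)) meta[paste0("true_", names(truth))] <- truth
  if (!is.null(attr(trace, "seed"))) meta$seed <- attr(trace, "seed")
  write_meta_csv(tibble(time_s = trace$time, signal = trace$signal),
                 path, meta)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  r <- read_meta_csv(path)
  out <- tibble(time = r$data$time_s, signal = r$data$signal)
  attr(out, "ligand_conc") <- r$meta$ligand_conc_M
  attr(out, "seed") <- r$meta$seed
  attr(out, "label") <- r$meta$label
  out
}

#' Write / read a sensorgram set as CSV
#'
#' Long layout (`analyte_conc_M`, `time_s`, `response_RU`) with the phase
#' windows in the commented header.
#'
#' @param data Long sensorgram tibble from [sim_sensorgram_set()].
#' @param path File path.
#' @return The path (writer) or an attributed tibble (reader).
#' @export
write_sensorgram_csv <- function(data, path) {
  meta <- list(t_assoc_s = attr(data, "t_assoc"),
               t_dissoc_s = attr(data, "t_dissoc"))
  truth <- attr(data, "truth")
  if (!is.null(truth)) meta[paste0("true_", names(truth))] <- truth
  if (!is.null(attr(data, "seed"))) meta$seed <- attr(data, "seed")
  write_meta_csv(tibble(analyte_conc_M = data$conc, time_s = data$time,
                        response_RU = data$response), path, meta)
}

#' @rdname write_sensorgram_csv
#' @export
read_sensorgram_csv <- function(path) {
  r <- read_meta_csv(path)
  out <- tibble(conc = r$data$analyte_conc_M, time = r$data$time_s,
                response = r$data$response_RU)
  out$phase <- ifelse(out$time <= r$meta$t_assoc_s, "association",
                      "dissociation")
  attr(out, "t_assoc") <- r$meta$t_assoc_s
  attr(out, "t_dissoc") <- r$meta$t_dissoc_s
  attr(out, "seed") <- r$meta$seed
  out
}

#' Write / read an ELISA panel as CSV
#'
#' Columns `variant`, `condition`, `replicate`, `signal`; the reference
#' variant id in the commented header.
#'
#' @param panel Panel tibble from [sim_elisa_panel()].
#' @param path File path.
#' @return The path (writer) or an attributed tibble (reader).
#' @export
write_elisa_csv <- function(panel, path) {
  meta <- list(reference = attr(panel, "reference"))
  if (!is.null(attr(panel, "seed"))) meta$seed <- attr(panel, "seed")
  write_meta_csv(panel[c("variant", "condition", "replicate", "signal")],
                 path, meta)
}

#' @rdname write_elisa_csv
#' @export
read_elisa_csv <- function(path) {
  r <- read_meta_csv(path)
  out <- r$data
  attr(out, "reference") <- r$meta$reference
  attr(out, "seed") <- r$meta$seed
  out
}
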