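#' Published rate constants of the tubulin-DARPin complexes
#'
#' The equilibrium and kinetic constants reported for the parent anti-tubulin
#' DARPin D1 and its affinity-matured variants (A-C2, the optimised triple
#' mutant TM-3, and C-cap-truncated/digested TM-3), as measured by
#' fluorescence spectroscopy and by surface plasmon resonance. These printed
#' values serve as inputs: truths for synthetic-data generation and operands
#' for the rate-ratio arithmetic.
#'
#' @return Tibble with columns `variant`, `method` (`"fluorescence"` /
#'   `"spr"`), `kd_titration_nM`, `kd_titration_se_nM`, `k_off`, `k_off_se`
#'   (1/s), `k_on`, `k_on_se` (1/(M s)), `probe_conc_nM` (fluorescence
#'   titration probe concentration).
#' @export
reference_rate_constants <- function() {
  tibble(
    variant = rep(c("D1", "A-C2", "TM-3", "TM-3-digested"), 2),
    method = rep(c("fluorescence", "spr"), each = 4),
    kd_titration_nM = c(127, 0.82, 0.90, 1.03, 300, NA, NA, NA),
    kd_titration_se_nM = c(12, 0.18, 0.19, 0.28, 30, NA, NA, NA),
    k_off = c(1.49, 0.0071, 0.0049, 0.0046, 0.22, 0.0041, 0.0025, 0.0027),
    k_off_se = c(0.07, 0.0002, 0.0002, 0.0001, 0.01, 0.0001, 0.0002, 0.0001),
    k_on = c(1.30e7, 1.60e7, 1.82e7, 2.67e7, 8e5, 1.2e6, 1.9e6, 1.7e6),
    k_on_se = c(NA, NA, NA, NA, 1.5e5, 0.2e6, 0.2e6, 0.1e6),
    probe_conc_nM = c(100, 15, 15, 15, NA, NA, NA, NA)
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate-fit-report for a set of binder variants: for each variant the
#' configured true constants drive the synthetic generators (equilibrium
#' titration, chase dissociation, pseudo-first-order association series),
#' the corresponding fits are run, and the results are assembled into a
#' rate-constant summary table with a titration/kinetic consistency flag.
#' Block failures are isolated: a variant whose fit fails is reported with
#' an `error` note instead of aborting the run.
#'
#' @param config A YAML file path or an equivalent nested list with entries:
#'   `seed` (integer), `noise_sd` (signal units, default 0.01), and
#'   `variants`, a named list where each element has `kd_nM`, `k_off`,
#'   `k_on`, `probe_conc_nM` and optionally `assoc_conc_nM` (association
#'   series concentrations; default 5 log-spaced multiples of the probe).
#' @return A list of class `darpkin_report`: `summary` (one tibble row per
#'   variant: fitted `kd_titration_nM`, `k_off`, `k_on`, `kd_kinetic_nM`,
#'   `consistency_ratio`, `consistency_pass`, `status`), `config_hash`,
#'   `seed`, `version`.
#' @examples
#' cfg <- list(seed = 1, noise_sd = 0.005,
#'             variants = list(D1 = list(kd_nM = 127, k_off = 1.49,
#'                                       k_on = 1.3e7, probe_conc_nM = 100)))
#' run_pipeline(cfg)$summary
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$variants) || length(cfg$variants) == 0) {
    abort("pipeline config must define at least one variant")
  }
  seed <- cfg$seed %||% 1
  noise <- cfg$noise_sd %||% 0.01

  rows <- purrr::imap(cfg$variants, function(v, name) {
    tryCatch({
      required <- c("kd_nM", "k_off", "k_on", "probe_conc_nM")
      miss <- setdiff(required, names(v))
      if (length(miss)) {
        abort(sprintf("variant '%s' lacks field(s): %s", name,
                      paste(miss, collapse = ", ")))
      }
      kd <- from_nM(v$kd_nM)
      probe <- from_nM(v$probe_conc_nM)
      vseed <- stream_seed(seed, name)

      tit <- sim_titration(kd = kd, probe_conc = probe, noise_sd = noise,
                           seed = vseed)
      tfit <- fit_titration(tit)

      chase <- sim_chase_trace(k_off = v$k_off, noise_sd = noise,
                               seed = vseed)
      cfit <- fit_monoexponential(chase, direction = "decay")

      aconc <- if (!is.null(v$assoc_conc_nM)) from_nM(v$assoc_conc_nM) else {
        probe * c(5, 10, 20, 40, 80)
      }
      assoc <- sim_association_series(k_on = v$k_on, k_off = v$k_off,
                                      probe_conc = probe, conc = aconc,
                                      noise_sd = noise, seed = vseed)
      afit <- fit_association_series(assoc)

      rates <- kd_from_rates(cfit$estimates[["k_obs"]],
                             afit$line$estimates[["k_on"]],
                             cfit$se[["k_obs"]],
                             afit$line$se[["k_on"]])
      cons <- kd_consistency(tfit$estimates[["kd"]], rates$kd)
      tibble(variant = name,
             kd_titration_nM = to_nM(tfit$estimates[["kd"]]),
             kd_titration_se_nM = to_nM(tfit$se[["kd"]]),
             k_off = rates$k_off, k_off_se = rates$k_off_se,
             k_on = rates$k_on, k_on_se = rates$k_on_se,
             kd_kinetic_nM = to_nM(rates$kd),
             kd_kinetic_se_nM = to_nM(rates$kd_se),
             consistency_ratio = cons$ratio,
             consistency_pass = cons$pass,
             status = "ok")
    }, error = function(e) {
      tibble(variant = name, kd_titration_nM = NA_real_,
             kd_titration_se_nM = NA_real_, k_off = NA_real_,
             k_off_se = NA_real_, k_on = NA_real_, k_on_se = NA_real_,
             kd_kinetic_nM = NA_real_, kd_kinetic_se_nM = NA_real_,
             consistency_ratio = NA_real_, consistency_pass = NA,
             status = paste("error:", conditionMessage(e)))
    })
  })
  structure(list(summary = dplyr::bind_rows(rows),
                 config_hash = rlang::hash(cfg), seed = seed,
                 version = as.character(utils::packageVersion("darpkin"))),
            class = "darpkin_report")
}

#' @export
print.darpkin_report <- function(x, ...) {
  cat(sprintf("<darpkin_report> seed %s, config %s, darpkin %s\n",
              x$seed, substr(x$config_hash, 1, 8), x$version))
  print(x$summary)
  invisible(x)
}

#' Structural comparison report
#'
#' Drives the structure-comparison operations over a configured pair of
#' structures: overall superposition, motif rotation, interface residues,
#' close contacts of the docked (unrotated) motif, buried surface area and
#' per-region B-factor means. Metric failures are isolated per row.
#'
#' @param config A YAML path or list with entries: `structures` (either
#'   `toy: {seed, motif_rotation_deg, clash_count_target}` or named PDB file
#'   paths `a:`, `b:`), `receptor_chain`, `binder_chain`, `motif_resno`,
#'   `body_resno` (integer vectors; for `toy` these default from the
#'   generator), optional `cutoff` (default 4) and `clash_threshold`
#'   (default 2).
#' @return A list of class `darpkin_structure_report`: `metrics` tibble
#'   (`metric`, `value`, `unit`, `status`, `note`), plus `config_hash`.
#' @export
compare_structures <- function(config) {
  cfg <- load_config(config)
  cutoff <- cfg$cutoff %||% 4
  clash_thr <- cfg$clash_threshold %||% 2

  if (!is.null(cfg$structures$toy)) {
    tc <- do.call(sim_toy_complex, cfg$structures$toy)
    complexed <- tc$complexed
    reference <- tc$reference
    receptor_chain <- tc$receptor_chain
    binder_chain <- tc$binder_chain
    motif_resno <- tc$motif_resno
    body_resno <- tc$body_resno
  } else {
    if (is.null(cfg$structures$a) || is.null(cfg$structures$b)) {
      abort("config must provide structures$toy or structures$a / structures$b")
    }
    complexed <- read_structure(cfg$structures$a)
    reference <- read_structure(cfg$structures$b)
    receptor_chain <- cfg$receptor_chain
    binder_chain <- cfg$binder_chain
    motif_resno <- cfg$motif_resno
    body_resno <- cfg$body_resno
  }
  binder_sel <- atom_selection(chain = binder_chain)
  receptor_sel <- atom_selection(chain = receptor_chain)
  body_sel <- atom_selection(chain = binder_chain, resno = body_resno)
  motif_sel <- atom_selection(chain = binder_chain, resno = motif_resno)

  metric <- function(name, unit, expr) {
    res <- tryCatch(list(value = expr, status = "ok", note = ""),
                    error = function(e) list(value = NA_real_,
                                             status = "error",
                                             note = conditionMessage(e)))
    tibble(metric = name, value = as.numeric(res$value)[1], unit = unit,
           status = res$status, note = res$note)
  }
  metrics <- dplyr::bind_rows(
    metric("binder_rmsd", "Angstrom",
           superpose(reference, complexed,
                     atom_selection(chain = binder_chain, atoms = "CA"))$rmsd),
    metric("motif_rotation", "degrees",
           motif_rotation(reference, complexed, body_sel,
                          motif_sel)$angle_deg),
    metric("interface_residues_binder", "count",
           nrow(interface_residues(complexed, receptor_sel, binder_sel,
                                   cutoff = cutoff)$residues_b)),
    metric("docked_motif_clashes", "count",
           nrow(count_close_contacts(
             structure_model(select_atoms(reference, motif_sel)),
             structure_model(select_atoms(reference, receptor_sel)),
             threshold = clash_thr))),
    metric("buried_surface", "Angstrom^2",
           buried_surface(complexed, receptor_sel, binder_sel)),
    metric("motif_mean_bfactor", "Angstrom^2",
           region_mean_bfactor(complexed, motif_sel)),
    metric("body_mean_bfactor", "Angstrom^2",
           region_mean_bfactor(complexed, body_sel))
  )
  structure(list(metrics = metrics, config_hash = rlang::hash(cfg)),
            class = "darpkin_structure_report")
}

#' @export
print.darpkin_structure_report <- function(x, ...) {
  cat(sprintf("<darpkin_structure_report> config %s\n",
              substr(x$config_hash, 1, 8)))
  print(x$metrics)
  invisible(x)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("no such config file: %s",
                                            config))
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a YAML file path or a list")
  }
}

#' Locate local copies of the deposited crystal structures
#'
#' The deposited entries for this system (4DRX: tubulin-D1 complex; 4DUI:
#' uncomplexed D1; 5EYL: uncomplexed TM-3; 5EYP: tubulin-A-C2 complex) are
#' too large to ship inside the package, so the structural reproduction
#' analysis reads them from a user-provided directory of PDB files, set via
#' `options(darpkin.pdb_dir = ...)` or the `DARPKIN_PDB_DIR` environment
#' variable.
#'
#' @param codes PDB accession codes to load.
#' @param dir Directory containing `<code>.pdb` files.
#' @return Named list of `structure_model`s.
#' @export
load_deposited_structures <- function(codes = c("4DRX", "4DUI", "5EYP"),
                                      dir = getOption(
                                        "darpkin.pdb_dir",
                                        Sys.getenv("DARPKIN_PDB_DIR", ""))) {
  paths <- file.path(dir, paste0(codes, ".pdb"))
  missing <- !nzchar(dir) | !file.exists(paths)
  if (any(missing)) {
    abort(paste0(
      "deposited coordinate file(s) not available locally: ",
      paste(codes[missing], collapse = ", "),
      ". Download the PDB entries and point options(darpkin.pdb_dir=) ",
      "or DARPKIN_PDB_DIR at the directory holding them."))
  }
  setNames(purrr::map(paths, read_structure), codes)
}
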