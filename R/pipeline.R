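#' degronstruct: structural and biophysical analysis of N-degron recognition
#'
#' See \code{\link{profile_structure}} for the end-to-end structural
#' pipeline, \code{\link{fit_itc}} / \code{\link{fit_melt}} for the binding
#' thermodynamics, and the \code{make_*} / \code{simulate_*} generators for
#' synthetic test oracles.
#'
#' @keywords internal
"_PACKAGE"

default_profile_config <- function() {
  list(expand = FALSE, symmetry_radius = 5.0,
       pi_thresholds = pi_pi_thresholds(),
       pi_cation_max_distance = 6.0, pi_cation_max_offset = 90,
       metals = "Zn", metal_cutoff = 3.0,
       hbond_cutoff = 3.5,
       water_cutoff = 4.0, water_anchor = NULL)
}

#' Profile a structure end-to-end
#'
#' Runs the full structural pipeline on one model: parse (if given a path),
#' optional crystallographic symmetry expansion, aromatic ring detection,
#' pi-pi and pi-cation contact classification, metal-site typing,
#' intermolecular hydrogen bonds (between atoms of different chains,
#' symmetry copies included), and a pocket-water census around an optional
#' anchor residue. Stage failures are captured in the report's \code{errors}
#' section rather than aborting the remaining stages.
#'
#' @param source a \code{\link{structure_model}} or a path/text accepted by
#'   \code{\link{parse_structure}}.
#' @param config named list overriding any defaults: \code{expand},
#'   \code{symmetry_radius}, \code{pi_thresholds},
#'   \code{pi_cation_max_distance}, \code{pi_cation_max_offset},
#'   \code{metals}, \code{metal_cutoff}, \code{hbond_cutoff},
#'   \code{water_cutoff}, \code{water_anchor} (list with \code{chain},
#'   \code{resno}).
#' @return list of class \code{profile_report}; serializable losslessly with
#'   \code{\link{write_report}}. All thresholds used are recorded under
#'   \code{$provenance}.
#' @export
profile_structure <- function(source, config = list()) {
  cfg <- utils::modifyList(default_profile_config(), config)
  model <- if (inherits(source, "structure_model")) source
           else parse_structure(source)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  if (isTRUE(cfg$expand))
    model <- stage("expand_symmetry",
                   expand_symmetry(model, cfg$symmetry_radius)) %||% model

  rings <- stage("rings", find_rings(model)) %||% list()
  ring_df <- if (length(rings)) do.call(rbind, lapply(rings, function(r)
    data.frame(chain = r$chain, resno = r$resno, resid = r$resid,
               ring_label = r$ring_label, planarity_rms = r$planarity_rms,
               sym_op = r$sym_op, stringsAsFactors = FALSE)))
    else data.frame()
  pi_pi <- stage("pi_pi",
                 find_pi_pi_contacts(model, thresholds = cfg$pi_thresholds))
  pi_cat <- stage("pi_cation",
                  find_pi_cation_contacts(
                    model, max_distance = cfg$pi_cation_max_distance,
                    max_offset = cfg$pi_cation_max_offset))
  sites <- stage("metal_sites",
                 find_metal_sites(model, metals = cfg$metals,
                                  cutoff = cfg$metal_cutoff)) %||% list()
  site_df <- if (length(sites)) do.call(rbind, lapply(sites, function(s)
    data.frame(element = s$metal$element, chain = s$metal$chain,
               resno = s$metal$resno, n_donors = nrow(s$donors),
               pattern = s$pattern, stringsAsFactors = FALSE)))
    else data.frame()
  hbonds <- stage("hbonds", {
    a <- model$atoms[!is_water_name(model$atoms$resid), , drop = FALSE]
    chains <- unique(a$chain)
    hb <- list()
    if (length(chains) > 1)
      for (i in seq_len(length(chains) - 1))
        for (j in seq(i + 1, length(chains)))
          hb[[length(hb) + 1]] <- find_hbonds(
            model, a[a$chain == chains[i], ], a[a$chain == chains[j], ],
            max_distance = cfg$hbond_cutoff)
    if (length(hb)) do.call(rbind, hb) else data.frame()
  })
  waters <- stage("waters", {
    if (!is.null(cfg$water_anchor)) {
      anchor <- select_atoms(model, chain = cfg$water_anchor$chain,
                             resno = cfg$water_anchor$resno)
      waters_near(model, anchor, cfg$water_cutoff)$count
    } else sum(is_water_name(model$atoms$resid) &
                 toupper(model$atoms$element) == "O" &
                 !model$atoms$is_symmetry_copy)
  })

  structure(list(
    id = model$id,
    counts = list(
      atoms = nrow(model$atoms),
      chains = length(unique(model$atoms$chain[!model$atoms$is_symmetry_copy])),
      symmetry_copy_atoms = sum(model$atoms$is_symmetry_copy),
      rings = length(rings),
      pi_pi_contacts = if (is.null(pi_pi)) 0L else nrow(pi_pi),
      pi_cation_contacts = if (is.null(pi_cat)) 0L else nrow(pi_cat),
      metal_sites = length(sites),
      hbonds = if (is.null(hbonds)) 0L else nrow(hbonds),
      waters = waters %||% 0L),
    rings = ring_df,
    pi_pi = pi_pi %||% data.frame(),
    pi_cation = pi_cat %||% data.frame(),
    metal_sites = site_df,
    hbonds = hbonds %||% data.frame(),
    provenance = c(list(package = "degronstruct",
                        version = as.character(utils::packageVersion("degronstruct"))),
                   cfg[c("expand", "symmetry_radius", "pi_cation_max_distance",
                         "pi_cation_max_offset", "metals", "metal_cutoff",
                         "hbond_cutoff", "water_cutoff")],
                   list(pi_thresholds = cfg$pi_thresholds)),
    errors = errors),
    class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat("profile_report '", x$id, "'\n", sep = "")
  utils::str(x$counts, no.list = TRUE)
  if (length(x$errors))
    cat("stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write a report as JSON
#'
#' Lossless, deterministic serialization (no timestamps) of profile or fit
#' reports: identical inputs and configuration produce byte-identical files.
#'
#' @param report a \code{profile_report} or any list-like report.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 8,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a contact table as TSV
#'
#' @param df a contact/site data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contacts_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit titration or melt data from CSV
#'
#' \code{mode = "itc"}: the CSV must hold a \code{heat} column (ucal per
#' injection); the protocol comes from \code{config} (\code{cell_conc} and
#' \code{syringe_conc} in mol/L, optional \code{cell_volume},
#' \code{injection_volume}). \code{mode = "tsa"}: the CSV must hold
#' \code{temperature} and \code{signal} columns; when
#' \code{config$reference_csv} names a second curve, its fit and the
#' resulting Tm shift are included.
#'
#' @param csv path to the data CSV.
#' @param mode "itc" or "tsa".
#' @param config named list (see Details above); for ITC also \code{fix_n},
#'   \code{exclude_first}.
#' @return a report list with fitted parameters, standard errors and
#'   convergence diagnostics.
#' @export
fit_thermo <- function(csv, mode = c("itc", "tsa"), config = list()) {
  mode <- match.arg(mode)
  dat <- utils::read.csv(csv)
  if (mode == "itc") {
    if (!"heat" %in% names(dat))
      stop("ITC CSV must contain a 'heat' column (ucal per injection)")
    if (is.null(config$cell_conc) || is.null(config$syringe_conc))
      stop("config must give cell_conc and syringe_conc (mol/L)")
    protocol <- itc_protocol(
      cell_conc = config$cell_conc, syringe_conc = config$syringe_conc,
      cell_volume = config$cell_volume %||% 1.4e-3,
      injection_volume = config$injection_volume %||% 5e-6,
      n_injections = nrow(dat))
    fit <- fit_itc(dat$heat, protocol,
                   fix_n = isTRUE(config$fix_n),
                   exclude_first = config$exclude_first %||% TRUE)
    list(mode = "itc", n = fit$n, kd_M = fit$kd, kd_uM = fit$kd * 1e6,
         dh_cal_mol = fit$dh, baseline_ucal = fit$baseline,
         se = as.list(fit$se), converged = fit$converged,
         c_value = fit$c_value, low_confidence = fit$low_confidence,
         kd_identifiable = fit$kd_identifiable, rss = fit$rss,
         protocol = unclass(protocol))
  } else {
    if (!all(c("temperature", "signal") %in% names(dat)))
      stop("TSA CSV must contain 'temperature' and 'signal' columns")
    fit <- fit_melt(dat$temperature, dat$signal)
    out <- list(mode = "tsa", tm_C = fit$tm,
                tm_derivative_C = fit$tm_derivative,
                low = fit$low, high = fit$high, slope = fit$slope,
                se = as.list(fit$se), converged = fit$converged)
    if (!is.null(config$reference_csv)) {
      ref <- utils::read.csv(config$reference_csv)
      rfit <- fit_melt(ref$temperature, ref$signal)
      out$reference_tm_C <- rfit$tm
      out$delta_tm_C <- delta_tm(fit, rfit)
    }
    out
  }
}
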