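#' Read and validate a run configuration
#'
#' The configuration is a YAML file with sections `phantom` (dims, shells,
#' noise_sigma), `scheme` (n_slices, r_sms, r_side), `dictionary`
#' (sh_order, n_dt), `recon` (lambda_tv, rho1, rho2, gamma, max_iter,
#' tolerances) and top-level `seed` and `out_dir`. Every field has a
#' default; unknown fields raise an error so typos do not silently
#' deconfigure a run.
#'
#' @param path YAML file path, or `NULL` for an all-defaults config.
#' @param overrides named list merged over the file values (flags beat
#'   file).
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path))
      stop_side("config file not found: ", path,
                class = "sidedmri_config_error")
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(
    seed = 1L, out_dir = "sidedmri_run",
    phantom = list(),                    # empty -> default_phantom()
    scheme = list(n_slices = 12L, r_sms = 3L, r_side = 2L),
    dictionary = list(sh_order = 8L, n_dt = 3L),
    recon = list(lambda_tv = 0.01, rho1 = 0.5, rho2 = 0.5,
                 gamma = c(0.9, 0.9, 1), max_iter = 100L,
                 eps1 = NULL, eps2 = NULL, dict_damping = 1e-6)
  )
  known <- names(defaults)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_side("unknown config field(s): ", paste(unknown, collapse = ", "),
              class = "sidedmri_config_error")
  full <- utils::modifyList(defaults, cfg)
  for (sec in c("scheme", "dictionary", "recon")) {
    bad <- setdiff(names(full[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop_side("unknown ", sec, " field(s): ", paste(bad, collapse = ", "),
                class = "sidedmri_config_error")
  }
  if (!is_count(full$seed + 1)) # allow 0
    stop_side("seed must be a non-negative integer",
              class = "sidedmri_config_error")
  structure(full, class = "run_config")
}

provenance <- function(cfg, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  cfg_rec <- unclass(cfg)
  cfg_rec$out_dir <- NULL              # a path, not a scientific parameter
  list(package = "sidedmri",
       version = as.character(utils::packageVersion("sidedmri")),
       seed = cfg$seed, config = cfg_rec, input_md5 = hashes)
}

write_sidecar <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `cfg$out_dir`, writes its outputs there
#' with a JSON provenance sidecar, and can be invoked on its own (in order:
#' phantom, plan, forward, recon, eval).
#'
#' @param cfg a [read_run_config()] result.
#' @return invisibly, a named list of the paths written.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_phantom <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- build_phantom_spec(cfg)
  sim <- synthesize(spec)
  paths <- file.path(cfg$out_dir, c(
    truth = "phantom_truth.nii.gz", noisy = "phantom_noisy.nii.gz",
    bvals = "phantom.bval", bvecs = "phantom.bvec",
    spec = "phantom_spec.json"))
  names(paths) <- c("truth", "noisy", "bvals", "bvecs", "spec")
  write_dwi(sim$truth, paths[["truth"]])
  write_dwi(sim$noisy, paths[["noisy"]])
  write_gradient_table(sim$gradients, paths[["bvals"]], paths[["bvecs"]])
  write_sidecar(list(dims = spec$dims, shells = spec$shells,
                     noise_sigma = spec$noise_sigma, seed = spec$seed,
                     provenance = provenance(cfg)), paths[["spec"]])
  invisible(as.list(paths))
}

build_phantom_spec <- function(cfg) {
  if (!length(cfg$phantom)) {
    spec <- default_phantom()
    spec$seed <- as.integer(cfg$seed)
    return(spec)
  }
  p <- cfg$phantom
  spec <- default_phantom()
  if (!is.null(p$noise_sigma)) spec$noise_sigma <- p$noise_sigma
  spec$seed <- as.integer(p$seed %||% cfg$seed)
  spec
}

#' @rdname pipeline_stages
#' @export
stage_plan <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- cfg$scheme
  scheme <- plan_side(make_grouping(s$n_slices, s$r_sms),
                      n_q = scheme_nq(cfg), r_side = s$r_side)
  path <- file.path(cfg$out_dir, "scheme.json")
  write_scheme(scheme, path)
  write_sidecar(provenance(cfg), file.path(cfg$out_dir, "scheme_prov.json"))
  invisible(list(scheme = path))
}

scheme_nq <- function(cfg) {
  spec <- build_phantom_spec(cfg)
  sum(vapply(spec$shells, function(s) as.integer(s[["n"]]), integer(1)))
}

#' @rdname pipeline_stages
#' @export
stage_forward <- function(cfg) {
  p <- file.path(cfg$out_dir, "phantom_truth.nii.gz")
  if (!file.exists(p))
    stop_side("phantom stage output missing: ", p,
              class = "sidedmri_config_error")
  spec <- build_phantom_spec(cfg)
  truth <- read_dwi(p)
  scheme <- read_scheme(file.path(cfg$out_dir, "scheme.json"))
  obs <- acquire(truth, scheme, noise_sigma = spec$noise_sigma,
                 seed = cfg$seed + 1L)
  paths <- list(obs = file.path(cfg$out_dir, "observation.nii.gz"),
                sidecar = file.path(cfg$out_dir, "observation.json"))
  write_observation(obs, paths$obs, paths$sidecar)
  write_sidecar(provenance(cfg, p), file.path(cfg$out_dir,
                                              "observation_prov.json"))
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_recon <- function(cfg) {
  obs <- read_observation(file.path(cfg$out_dir, "observation.nii.gz"),
                          file.path(cfg$out_dir, "observation.json"))
  gt <- read_gradient_table(file.path(cfg$out_dir, "phantom.bval"),
                            file.path(cfg$out_dir, "phantom.bvec"))
  d <- cfg$dictionary
  dict <- build_dictionary(gt, spectrum_grid(n_dt = d$n_dt),
                           sh_order = d$sh_order)
  r <- cfg$recon
  rcfg <- recon_config(lambda_tv = r$lambda_tv, rho1 = r$rho1,
                       rho2 = r$rho2,
                       weights = tv_weights(r$gamma[1], r$gamma[2],
                                            r$gamma[3]),
                       eps1 = r$eps1, eps2 = r$eps2,
                       max_iter = r$max_iter, dict_damping = r$dict_damping)
  recon <- reconstruct(obs, dict, rcfg)
  paths <- list(recon = file.path(cfg$out_dir, "recon.nii.gz"),
                report = file.path(cfg$out_dir, "recon_report.json"))
  write_dwi(recon$E, paths$recon)
  write_sidecar(list(stop_reason = recon$stop_reason,
                     iterations = nrow(recon$history),
                     history = recon$history,
                     config = r, provenance = provenance(cfg)),
                paths$report)
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_eval <- function(cfg) {
  truth <- read_dwi(file.path(cfg$out_dir, "phantom_truth.nii.gz"))
  recon <- read_dwi(file.path(cfg$out_dir, "recon.nii.gz"))
  gt <- read_gradient_table(file.path(cfg$out_dir, "phantom.bval"),
                            file.path(cfg$out_dir, "phantom.bvec"))
  rep <- metric_report(recon, truth, gradients = gt)
  path <- file.path(cfg$out_dir, "eval.json")
  write_sidecar(list(nmse = rep$nmse, psnr = rep$psnr, ssim = rep$ssim,
                     per_shell = rep$per_shell,
                     provenance = provenance(cfg)), path)
  invisible(list(eval = path, report = rep))
}

#' Run the full phantom-to-evaluation pipeline
#'
#' Executes phantom generation, SIDE planning, forward simulation,
#' reconstruction and evaluation in order, writing every intermediate with
#' a JSON provenance sidecar (input hashes, configuration, package version,
#' seed). Deterministic under a fixed seed. On stage failure the partial
#' outputs are retained next to a `FAILED` marker naming the stage.
#'
#' @param cfg a [read_run_config()] result, or a path to a YAML config.
#' @param overrides named list merged over the config.
#' @return invisibly, the [stage_eval()] result.
#' @export
run_pipeline <- function(cfg = NULL, overrides = list()) {
  if (is.null(cfg) || is.character(cfg))
    cfg <- read_run_config(cfg, overrides)
  stages <- list(phantom = stage_phantom, plan = stage_plan,
                 forward = stage_forward, recon = stage_recon,
                 eval = stage_eval)
  out <- NULL
  for (nm in names(stages)) {
    out <- tryCatch(stages[[nm]](cfg), error = function(e) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste0("stage ", nm, ": ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop_side("pipeline failed at stage '", nm, "': ",
                conditionMessage(e))
    })
  }
  invisible(out)
}
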