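#' Pipeline run configuration
#'
#' Nested per-stage settings plus one global seed. Every stochastic stage
#' receives a seed derived deterministically from the global seed and the
#' stage name (see [derive_seed()]), so a run is reproducible end to end.
#'
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed).
#' @param phantom list: `shape`, `n_train`, `n_test`, `snr`.
#' @param qspace list: `n_dirs`, `n_b0`, `bval`.
#' @param discus list: encoder size and pre-training budget.
#' @param vinn list: segmenter size, training scheme, steps, views.
#' @param verbose print stage progress.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("dwiseg_run_"),
                       phantom = list(), qspace = list(), discus = list(),
                       vinn = list(), verbose = FALSE) {
  defaults <- list(
    phantom = list(shape = c(64L, 64L, 64L), n_train = 2L, n_test = 1L,
                   snr = 25),
    qspace = list(n_dirs = 90L, n_b0 = 3L, bval = 1000),
    discus = list(L = 16L, hidden_width = 32L, n_voxels = 8000L,
                  epochs = 10L, batch_size = 2048L, lr = 0.005),
    vinn = list(filters = 16L, steps = NULL, lr = 1e-3,
                scheme = "pretrain_frozen", batch_size = 2L,
                views = c("axial", "coronal", "sagittal"))
  )
  merge_into <- function(def, user) { def[names(user)] <- user; def }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 phantom = merge_into(defaults$phantom, phantom),
                 qspace = merge_into(defaults$qspace, qspace),
                 discus = merge_into(defaults$discus, discus),
                 vinn = merge_into(defaults$vinn, vinn),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Derive a stage seed from the global seed
#'
#' Stable polynomial string hash (31-adic over the stage name's character
#' codes, modulo 2^31 - 1) combined with the global seed; platform- and
#' session-independent.
#'
#' @param seed global seed.
#' @param stage stage name.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.pipeline_stages <- c("simulate", "pretrain", "train", "segment", "evaluate")

#' Run the desk-scale pipeline
#'
#' Executes the requested stages in order (simulate -> pretrain -> train ->
#' segment -> evaluate), writing per-stage artifacts under
#' `config$out_dir/<stage>/` and a manifest listing every output file with
#' its MD5 checksum. Later stages read the artifacts of earlier stages from
#' disk; a missing upstream artifact raises a dependency error naming the
#' stage.
#'
#' @param config a [run_config()].
#' @param stages character vector of stage names to execute.
#' @return the run manifest (invisibly written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, stages = .pipeline_stages) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$config_hash <- config_hash(config)
  manifest$package_version <- as.character(utils::packageVersion("dwiseg"))
  for (stage in .pipeline_stages[.pipeline_stages %in% stages]) {
    if (config$verbose) message("[dwiseg] stage: ", stage)
    files <- switch(stage,
      simulate = stage_simulate(config),
      pretrain = stage_pretrain(config),
      train = stage_train(config),
      segment = stage_segment(config),
      evaluate = stage_evaluate(config))
    manifest$stages[[stage]] <- list(
      seed = derive_seed(config$seed, stage),
      files = as.list(tools::md5sum(files)))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config)), f)
  unname(tools::md5sum(f))
}

dep_error <- function(stage, what) {
  stop(errorCondition(
    sprintf("dependency error: stage '%s' requires %s (run the upstream stage first)",
            stage, what),
    class = c("dwiseg_dependency_error", "error", "condition")))
}

participant_ids <- function(config) {
  n <- config$phantom$n_train + config$phantom$n_test
  sprintf("sub-%02d", seq_len(n))
}

train_ids <- function(config) participant_ids(config)[seq_len(config$phantom$n_train)]
test_ids <- function(config) setdiff(participant_ids(config), train_ids(config))

stage_simulate <- function(config) {
  out <- file.path(config$out_dir, "simulate")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  scheme <- single_shell_scheme(config$qspace$n_dirs, config$qspace$bval,
                                config$qspace$n_b0,
                                seed = derive_seed(config$seed, "scheme"))
  files <- character()
  for (pid in participant_ids(config)) {
    pdir <- file.path(out, pid)
    dir.create(pdir, showWarnings = FALSE)
    ph <- build_phantom(config$phantom$shape,
                        seed = derive_seed(config$seed, paste0("phantom_", pid)))
    dwi <- simulate_acquisition(ph, scheme, snr = config$phantom$snr,
                                seed = derive_seed(config$seed, paste0("acq_", pid)))
    p <- function(name) file.path(pdir, name)
    write_nifti(dwi$data, p("dwi.nii.gz"), spacing = ph$spacing,
                datatype = "float32")
    write_nifti(dwi$mean_b0, p("meanb0.nii.gz"), spacing = ph$spacing,
                datatype = "float32")
    write_volume(ph$labels, p("labels.nii.gz"), spacing = ph$spacing,
                 labels = TRUE)
    write_nifti(ph$mask, p("mask.nii.gz"), spacing = ph$spacing,
                datatype = "uint8")
    write_gradient_table(scheme, p("dwi.bvec"), p("dwi.bval"))
    files <- c(files, p(c("dwi.nii.gz", "meanb0.nii.gz", "labels.nii.gz",
                          "mask.nii.gz", "dwi.bvec", "dwi.bval")))
  }
  files
}

load_participant <- function(config, pid, stage, labels = TRUE) {
  pdir <- file.path(config$out_dir, "simulate", pid)
  if (!dir.exists(pdir)) dep_error(stage, paste0("simulated data for ", pid))
  scheme <- read_gradient_table(file.path(pdir, "dwi.bvec"),
                                file.path(pdir, "dwi.bval"))
  dwi_v <- read_volume(file.path(pdir, "dwi.nii.gz"))
  b0_v <- read_volume(file.path(pdir, "meanb0.nii.gz"))
  mask_v <- read_volume(file.path(pdir, "mask.nii.gz"), labels = TRUE)
  check_alignment(dwi_v, b0_v, "dwi", "mean b0")
  check_alignment(dwi_v, mask_v, "dwi", "mask")
  check_dwi_scheme(dwi_v$data, scheme)
  lab <- NULL
  if (labels) {
    lab_v <- read_volume(file.path(pdir, "labels.nii.gz"), labels = TRUE)
    check_alignment(dwi_v, lab_v, "dwi", "labels")
    lab <- lab_v$data
  }
  list(dwi = structure(list(data = dwi_v$data, scheme = scheme,
                            mean_b0 = b0_v$data, spacing = dwi_v$spacing[1]),
                       class = "dwi_volume"),
       mask = array(mask_v$data > 0, dim(mask_v$data)),
       labels = lab, spacing = dwi_v$spacing[1])
}

participant_case <- function(config, pid, stage, enc_cfg) {
  pl <- load_participant(config, pid, stage)
  ph <- list(mask = pl$mask,
             labels = if (is.null(pl$labels)) array(0L, dim(pl$mask))
                      else pl$labels,
             spacing = pl$spacing)
  prepare_case(ph, pl$dwi, enc_cfg)
}

encoder_cfg_from_config <- function(config) {
  encoder_config(L = config$discus$L, hidden_width = config$discus$hidden_width)
}

stage_pretrain <- function(config) {
  out <- file.path(config$out_dir, "pretrain")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- derive_seed(config$seed, "pretrain")
  enc_cfg <- encoder_cfg_from_config(config)
  sig <- list()
  for (pid in train_ids(config)) {
    pl <- load_participant(config, pid, "pretrain", labels = FALSE)
    norm <- normalize_case_signals(pl$dwi, pl$mask, enc_cfg)
    sig[[pid]] <- norm[, !pl$dwi$scheme$is_b0, drop = FALSE]
  }
  scheme <- load_participant(config, train_ids(config)[1], "pretrain",
                             labels = FALSE)$dwi$scheme
  dwi_scheme <- acquisition_scheme(scheme$bvecs[!scheme$is_b0, , drop = FALSE],
                                   scheme$bvals[!scheme$is_b0])
  sig <- do.call(rbind, sig)
  n_vox <- min(config$discus$n_voxels, nrow(sig))
  keep <- with_seed(seed, sample.int(nrow(sig), n_vox))
  fit <- pretrain_reconstruction(sig[keep, , drop = FALSE], dwi_scheme,
                                 config = enc_cfg, seed = seed,
                                 epochs = config$discus$epochs,
                                 batch_size = config$discus$batch_size,
                                 lr = config$discus$lr,
                                 verbose = config$verbose)
  ck <- file.path(out, "encoder.rds")
  saveRDS(list(params = fit$params, scheme_fingerprint = scheme_fingerprint(scheme),
               history = fit$history, baseline_val_mse = fit$baseline_val_mse),
          ck)
  hist_path <- file.path(out, "history.tsv")
  utils::write.table(fit$history, hist_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  c(ck, hist_path)
}

scheme_fingerprint <- function(scheme) {
  f <- tempfile()
  on.exit(unlink(f))
  write_gradient_table(scheme, f, paste0(f, ".bval"))
  on.exit(unlink(paste0(f, ".bval")), add = TRUE)
  paste(tools::md5sum(c(f, paste0(f, ".bval"))), collapse = "")
}

stage_train <- function(config) {
  out <- file.path(config$out_dir, "train")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  enc_cfg <- encoder_cfg_from_config(config)
  scheme_name <- config$vinn$scheme
  if (scheme_name == "pretrain_frozen") {
    ck <- file.path(config$out_dir, "pretrain", "encoder.rds")
    if (!file.exists(ck)) dep_error("train", "a pre-trained encoder checkpoint")
    encoder <- readRDS(ck)$params
  } else {
    encoder <- discus_init(enc_cfg, seed = derive_seed(config$seed, "encoder_init"))
  }
  cases <- lapply(train_ids(config), function(pid)
    participant_case(config, pid, "train", enc_cfg))
  S <- max(vapply(cases, function(cs) max(cs$labels), 0L)) + 1L
  vcfg <- vinn_config(L = enc_cfg$L, S = S, filters = config$vinn$filters,
                      lr = config$vinn$lr, batch_size = config$vinn$batch_size,
                      views = config$vinn$views)
  files <- character()
  for (vw in vcfg$views) {
    fit <- train_view(vw, cases, encoder, scheme = scheme_name, config = vcfg,
                      seed = derive_seed(config$seed, paste0("train_", vw)),
                      steps = config$vinn$steps, verbose = config$verbose)
    p <- file.path(out, paste0(vw, ".rds"))
    saveRDS(fit, p)
    files <- c(files, p)
  }
  files
}

load_view_models <- function(config, stage) {
  tdir <- file.path(config$out_dir, "train")
  views <- config$vinn$views
  paths <- file.path(tdir, paste0(views, ".rds"))
  if (!all(file.exists(paths)))
    dep_error(stage, "trained per-view checkpoints")
  stats::setNames(lapply(paths, readRDS), views)
}

stage_segment <- function(config) {
  out <- file.path(config$out_dir, "segment")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  vms <- load_view_models(config, "segment")
  enc_cfg <- vms[[1]]$encoder$config
  files <- character()
  for (pid in test_ids(config)) {
    cs <- participant_case(config, pid, "segment", enc_cfg)
    pred <- predict_segmentation(cs, vms)
    p <- file.path(out, paste0(pid, "_seg.nii.gz"))
    write_volume(pred$labels, p, spacing = cs$spacing, labels = TRUE)
    files <- c(files, p)
  }
  files
}

#' Default phantom label merge and group tables
#'
#' The phantom's own small label inventory: identity merge, and a grouping of
#' each tissue label into its region group. Shipped as data so users can
#' supply their own tables for other inventories.
#' @return named vector (merge map / group map).
#' @export
default_merge_map <- function() stats::setNames(0:5, 0:5)

#' @rdname default_merge_map
#' @export
default_group_map <- function() {
  c(`1` = "white matter", `2` = "cortical GM", `3` = "subcortical GM",
    `4` = "Vent-CSF", `5` = "cerebellum")
}

stage_evaluate <- function(config) {
  out <- file.path(config$out_dir, "evaluate")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seg_dir <- file.path(config$out_dir, "segment")
  recs <- list()
  for (pid in test_ids(config)) {
    sp <- file.path(seg_dir, paste0(pid, "_seg.nii.gz"))
    if (!file.exists(sp)) dep_error("evaluate", paste0("segmentation for ", pid))
    pred <- read_volume(sp, labels = TRUE)
    ref <- read_volume(file.path(config$out_dir, "simulate", pid,
                                 "labels.nii.gz"), labels = TRUE)
    check_alignment(pred, ref, "prediction", "reference")
    recs[[pid]] <- evaluate_segmentation(pred$data, ref$data,
                                         spacing_mm = pred$spacing[1],
                                         participant = pid,
                                         merge_map = default_merge_map())
  }
  records <- do.call(rbind, recs)
  rp <- file.path(out, "records.tsv")
  utils::write.table(records, rp, sep = "\t", row.names = FALSE, quote = FALSE)
  groups <- group_metrics(records, default_group_map())
  gp <- file.path(out, "groups.tsv")
  utils::write.table(groups, gp, sep = "\t", row.names = FALSE, quote = FALSE)
  c(rp, gp)
}

#' Build a segmentation case from NIfTI / bvec / bval files
#'
#' Reads a 4D diffusion series with its FSL gradient table, a binary brain
#' mask and a mean b0 volume (and, optionally, reference labels), validates
#' their alignment, and prepares the case for [predict_segmentation()] or
#' [evaluate_segmentation()].
#'
#' @param dwi_path 4D NIfTI diffusion series.
#' @param bvec_path,bval_path FSL-dialect gradient table.
#' @param mask_path binary brain mask (integer NIfTI).
#' @param b0_path mean b0 volume.
#' @param labels_path optional reference label volume.
#' @param config an [encoder_config()] (signal clip).
#' @return a `seg_case` (see [prepare_case()]).
#' @export
case_from_files <- function(dwi_path, bvec_path, bval_path, mask_path,
                            b0_path, labels_path = NULL,
                            config = encoder_config()) {
  scheme <- read_gradient_table(bvec_path, bval_path)
  dwi_v <- read_volume(dwi_path)
  b0_v <- read_volume(b0_path)
  mask_v <- read_volume(mask_path, labels = TRUE)
  check_alignment(dwi_v, b0_v, "dwi", "mean b0")
  check_alignment(dwi_v, mask_v, "dwi", "mask")
  check_dwi_scheme(dwi_v$data, scheme)
  lab <- NULL
  if (!is.null(labels_path)) {
    lab_v <- read_volume(labels_path, labels = TRUE)
    check_alignment(dwi_v, lab_v, "dwi", "labels")
    lab <- lab_v$data
  }
  mask <- array(mask_v$data > 0, dim(mask_v$data))
  ph <- list(mask = mask,
             labels = if (is.null(lab)) array(0L, dim(mask)) else lab,
             spacing = dwi_v$spacing[1])
  dwi <- structure(list(data = dwi_v$data, scheme = scheme,
                        mean_b0 = b0_v$data, spacing = dwi_v$spacing[1]),
                   class = "dwi_volume")
  prepare_case(ph, dwi, config)
}

#' Segment a single acquisition from files
#'
#' Standalone inference: loads trained per-view checkpoints from a pipeline
#' `train/` directory, optionally restricts the observation set to the `k`
#' diffusion directions with maximum angular coverage, and writes the label
#' volume.
#'
#' @param dwi_path,bvec_path,bval_path,mask_path,b0_path input files (see
#'   [case_from_files()]).
#' @param checkpoint_dir directory holding `<view>.rds` checkpoints from
#'   [train_view()] / the pipeline train stage.
#' @param directions optional number of diffusion directions to use.
#' @param out_path output NIfTI path.
#' @return the predicted label volume, invisibly.
#' @export
segment_files <- function(dwi_path, bvec_path, bval_path, mask_path, b0_path,
                          checkpoint_dir, directions = NULL,
                          out_path = "seg.nii.gz") {
  paths <- list.files(checkpoint_dir, pattern = "^(axial|coronal|sagittal)\\.rds$",
                      full.names = TRUE)
  if (length(paths) == 0L)
    dep_error("segment", paste0("per-view checkpoints under ", checkpoint_dir))
  vms <- lapply(paths, readRDS)
  names(vms) <- sub("\\.rds$", "", basename(paths))
  enc_cfg <- vms[[1]]$encoder$config
  cs <- case_from_files(dwi_path, bvec_path, bval_path, mask_path, b0_path,
                        config = enc_cfg)
  sub <- NULL
  if (!is.null(directions))
    sub <- subsample_max_coverage(cs$scheme, as.integer(directions))
  pred <- predict_segmentation(cs, vms, subset_indices = sub)
  write_volume(pred$labels, out_path, spacing = cs$spacing, labels = TRUE)
  invisible(pred$labels)
}

# ---- command-line interface -------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate`, `pretrain`, `train`, `segment`, `evaluate`,
#' `report` (pipeline stages against a run directory), usable as
#' `Rscript -e 'dwiseg::dwiseg_cli()' <subcommand> --out-dir <dir> --seed <n>`.
#' Exit codes: 0 success, 2 usage error, 3 format error, 4 dependency error.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return exit status, invisibly; as a side effect writes stage artifacts.
#' @export
dwiseg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: dwiseg <simulate|pretrain|train|segment|evaluate|report>",
                 "[--out-dir DIR] [--seed N] [--config FILE.json] [--verbose]")
  if (length(args) < 1L || !args[1] %in% c(.pipeline_stages, "report")) {
    message(usage)
    return(invisible(2L))
  }
  sub <- args[1]
  spec <- list(
    optparse::make_option("--out-dir", type = "character",
                          default = "dwiseg_run", dest = "out_dir"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--verbose", action = "store_true", default = FALSE),
    # standalone `segment` on explicit files
    optparse::make_option("--dwi", type = "character", default = NULL),
    optparse::make_option("--bvec", type = "character", default = NULL),
    optparse::make_option("--bval", type = "character", default = NULL),
    optparse::make_option("--mask", type = "character", default = NULL),
    optparse::make_option("--b0", type = "character", default = NULL,
                          dest = "b0"),
    optparse::make_option("--checkpoint-dir", type = "character",
                          default = NULL, dest = "checkpoint_dir"),
    optparse::make_option("--directions", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = "seg.nii.gz")
  )
  opts <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args[-1]),
    error = function(e) { message(usage); NULL })
  if (is.null(opts)) return(invisible(2L))
  overrides <- list()
  if (!is.null(opts$config)) {
    overrides <- tryCatch(jsonlite::read_json(opts$config, simplifyVector = TRUE),
                          error = function(e) {
                            message("format error reading config: ",
                                    conditionMessage(e))
                            NULL
                          })
    if (is.null(overrides)) return(invisible(3L))
  }
  cfg <- run_config(seed = opts$seed, out_dir = opts$out_dir,
                    phantom = overrides$phantom %||% list(),
                    qspace = overrides$qspace %||% list(),
                    discus = overrides$discus %||% list(),
                    vinn = overrides$vinn %||% list(),
                    verbose = opts$verbose)
  if (sub == "segment" && !is.null(opts$dwi)) {
    need <- c("bvec", "bval", "mask", "b0", "checkpoint_dir")
    miss <- need[vapply(need, function(nm) is.null(opts[[nm]]), TRUE)]
    if (length(miss)) {
      message("usage error: standalone segment requires --",
              paste(miss, collapse = " --"))
      return(invisible(2L))
    }
    status <- tryCatch({
      segment_files(opts$dwi, opts$bvec, opts$bval, opts$mask, opts$b0,
                    opts$checkpoint_dir, directions = opts$directions,
                    out_path = opts$out)
      0L
    },
    dwiseg_dependency_error = function(e) { message(conditionMessage(e)); 4L },
    error = function(e) { message("error: ", conditionMessage(e)); 3L })
    return(invisible(status))
  }
  if (sub == "report") {
    gp <- file.path(cfg$out_dir, "evaluate", "groups.tsv")
    if (!file.exists(gp)) {
      message("dependency error: no evaluation table at ", gp)
      return(invisible(4L))
    }
    print(utils::read.delim(gp))
    return(invisible(0L))
  }
  status <- tryCatch({
    run_pipeline(cfg, stages = sub)
    0L
  },
  dwiseg_dependency_error = function(e) { message(conditionMessage(e)); 4L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
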