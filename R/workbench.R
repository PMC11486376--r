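# Run orchestration: validated configuration, cross-validation fold plans,
# and the config-driven train / generate / evaluate commands.

run_config_defaults <- function() {
  list(
    run = list(out_dir = "cpdm_run", seed = 1, folds = 15),
    image = list(size = 16, axis = "sagittal", mode = "max"),
    omics = list(fraction = 0.10, rank = 17, seed = 1),
    diffusion = list(T = 50, beta_start = 0.004, beta_end = 0.18,
                     sigma_mode = "beta"),
    model = list(depth = 2, base_channels = 8, time_dim = 16, tokens = 4,
                 d_k = 8, extension = "dense", gate_init = 0,
                 aux_cond = TRUE),
    train = list(epochs = 30, batch_size = 16, lr = 2e-3),
    evaluate = list(extractor = "pixels", ssim_mode = "global",
                    n_batches = 2)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (or takes a list), checks every key against
#' the known schema — unknown keys are rejected, so typos fail before any
#' compute — and fills unset keys with package defaults.
#'
#' @param x path to a YAML file, or a named list, or NULL for pure defaults.
#' @return Nested list of class `"run_config"` with attribute
#'   `"config_hash"`.
#' @export
run_config <- function(x = NULL) {
  cfg <- run_config_defaults()
  user <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else if (is.list(x)) x
          else stop("`x` must be a path, list or NULL", call. = FALSE)
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop(sprintf("unknown config section '%s'", sec), call. = FALSE)
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop(sprintf("unknown config key '%s.%s'", sec, key), call. = FALSE)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# polynomial rolling hash over the serialized object (31-bit arithmetic,
# exact in doubles); identifies a config in run manifests without external
# dependencies
config_hash <- function(x) {
  attr(x, "config_hash") <- NULL
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in raw) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Plan cross-validation folds
#'
#' Seeded shuffle followed by contiguous partition into `k` folds of size
#' `ceiling(N/k)` or `floor(N/k)`. Splitting 58 ids into 15 folds yields 13
#' test folds of 4 (training complement 54) and 2 of 3 (complement 55) —
#' the fold arithmetic of a 58-sample paired cohort.
#'
#' @param ids vector of sample identifiers.
#' @param k number of folds (`2 <= k <= length(ids)`).
#' @param seed integer seed for the shuffle (independent of model seeding).
#' @return Object of class `"fold_plan"`: list with `k`, `folds` (list of
#'   test-id vectors) and `train` (their complements).
#' @export
make_folds <- function(ids, k = 15, seed = 1) {
  N <- length(ids)
  if (k > N) stop("`k` cannot exceed the number of ids", call. = FALSE)
  if (k < 2)
    stop("`k` must be >= 2: a single fold leaves an empty training set",
         call. = FALSE)
  set.seed(as.integer(seed))
  shuffled <- sample(ids)
  sizes <- rep(floor(N / k), k)
  extra <- N - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  folds <- lapply(seq_len(k), function(i) shuffled[starts[i]:ends[i]])
  structure(list(k = k, folds = folds,
                 train = lapply(folds, function(f) setdiff(ids, f)),
                 seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sz <- lengths(x$folds)
  cat(sprintf("Fold plan: %d folds over %d ids (test sizes %s)\n",
              x$k, sum(sz), paste(sort(unique(sz)), collapse = "/")))
  invisible(x)
}

write_manifest <- function(dir, cfg, extra = list()) {
  man <- c(list(config_hash = attr(cfg, "config_hash"),
                seed = cfg$run$seed,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Config-driven training run
#'
#' Builds fixtures (or takes prepared data), trains one model per requested
#' fold — or a single model on everything when `folds = 0` — and writes
#' checkpoints, a JSON-lines loss log and a manifest carrying the config
#' hash and seed.
#'
#' @param cfg a [run_config()].
#' @param images `n x n x N` array in `[-1, 1]`; NULL builds synthetic
#'   fixtures from the config.
#' @param tau `N x R` condition matrix (required with `images`).
#' @param folds number of folds to actually train (0 = no folding; the
#'   full fold plan is still written).
#' @return Invisibly, a list of fitted models (one per trained fold).
#' @export
run_train <- function(cfg = run_config(), images = NULL, tau = NULL,
                      folds = 0) {
  dir.create(cfg$run$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(images)) {
    fx <- make_fixtures(fixture_spec(size = cfg$image$size,
                                     seed = cfg$run$seed))
    images <- fx$images * 2 - 1
    tau <- condition_scores(fx$factors)
  }
  N <- dim(images)[3]
  ids <- seq_len(N)
  plan <- make_folds(ids, k = min(cfg$run$folds, N),
                     seed = derive_seed(cfg$run$seed, 501))
  saveRDS(plan, file.path(cfg$run$out_dir, "fold_plan.rds"))

  sched <- noise_schedule(cfg$diffusion$T, beta_start = cfg$diffusion$beta_start,
                          beta_end = cfg$diffusion$beta_end,
                          sigma_mode = cfg$diffusion$sigma_mode)
  dcfg <- denoiser_config(n = dim(images)[1], R = ncol(tau),
                          depth = cfg$model$depth,
                          base_channels = cfg$model$base_channels,
                          time_dim = cfg$model$time_dim,
                          n_tokens = cfg$model$tokens, d_k = cfg$model$d_k,
                          extension = cfg$model$extension,
                          gate_init = cfg$model$gate_init,
                          aux_cond = cfg$model$aux_cond)
  log_path <- file.path(cfg$run$out_dir, "loss_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_con <- file(log_path, "a")
  on.exit(close(log_con))

  train_sets <- if (folds > 0) lapply(plan$train[seq_len(folds)], identity)
                else list(ids)
  fits <- vector("list", length(train_sets))
  for (f in seq_along(train_sets)) {
    idx <- train_sets[[f]]
    fit <- cpdm(images[, , idx, drop = FALSE], tau[idx, , drop = FALSE],
                schedule = sched, epochs = cfg$train$epochs,
                batch_size = cfg$train$batch_size, lr = cfg$train$lr,
                config = dcfg, seed = derive_seed(cfg$run$seed, 600 + f))
    for (ep in seq_along(fit$loss_history))
      writeLines(jsonlite::toJSON(list(fold = f, epoch = ep,
                                       loss = fit$loss_history[ep],
                                       config_hash = attr(cfg, "config_hash"),
                                       seed = cfg$run$seed),
                                  auto_unbox = TRUE), log_con)
    save_checkpoint(fit, file.path(cfg$run$out_dir,
                                   sprintf("model_fold%02d.rds", f)))
    fits[[f]] <- fit
  }
  write_manifest(cfg$run$out_dir, cfg,
                 list(n_models = length(fits), command = "train"))
  invisible(fits)
}

#' Config-driven generation
#'
#' Loads (or takes) a fitted model and generates one image per supplied
#' condition vector via the ancestral sampler, writing PNG + float
#' containers and a manifest.
#'
#' @param cfg a [run_config()].
#' @param fit a fitted [cpdm()]; by default the first fold checkpoint in
#'   the run directory.
#' @param tau condition matrix, one image per row.
#' @param seed sampling seed (default: derived from the config seed).
#' @return Invisibly, the generated `n x n x nrow(tau)` array (unit range).
#' @export
run_generate <- function(cfg = run_config(), fit = NULL, tau, seed = NULL) {
  if (is.null(fit)) {
    ckpt <- file.path(cfg$run$out_dir, "model_fold01.rds")
    if (!file.exists(ckpt))
      stop(sprintf("no checkpoint at '%s'; run_train() first", ckpt),
           call. = FALSE)
    fit <- load_checkpoint(ckpt)
  }
  if (is.null(seed)) seed <- derive_seed(cfg$run$seed, 701)
  tau <- as.matrix(tau)
  if (ncol(tau) != fit$R)
    stop(sprintf("condition matrix has %d factors but the checkpoint expects %d",
                 ncol(tau), fit$R), call. = FALSE)
  imgs <- simulate(fit, nsim = nrow(tau), seed = seed, tau = tau,
                   output = "unit")
  gen_dir <- file.path(cfg$run$out_dir, "generated")
  dir.create(gen_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(dim(imgs)[3])) {
    write_image_png(imgs[, , i], file.path(gen_dir, sprintf("gen%03d.png", i)))
    write_image_float(imgs[, , i], file.path(gen_dir, sprintf("gen%03d.txt", i)))
  }
  write_manifest(gen_dir, cfg, list(n_images = dim(imgs)[3],
                                    command = "generate", seed = seed))
  invisible(imgs)
}

#' Config-driven evaluation
#'
#' Computes the metric report for a generated set against a real set and
#' writes it as JSON with the settings, config hash and seed.
#'
#' @param cfg a [run_config()].
#' @param real,generated image stacks in `[0, 1]`.
#' @return The [evaluate_images()] report, invisibly.
#' @export
run_evaluate <- function(cfg = run_config(), real, generated) {
  rep <- evaluate_images(real, generated,
                         extractor = cfg$evaluate$extractor,
                         n_batches = cfg$evaluate$n_batches,
                         ssim_mode = cfg$evaluate$ssim_mode)
  dir.create(cfg$run$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(rep[c("fid", "fid_std", "mse", "ssim")],
                         list(settings = rep$settings,
                              config_hash = attr(cfg, "config_hash"),
                              seed = cfg$run$seed)),
                       file.path(cfg$run$out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rep)
}
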