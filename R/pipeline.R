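# Build a config object from a parameter list, keeping only known fields.
cfg_from_params <- function(constructor, params) {
  if (is.null(params)) params <- list()
  known <- intersect(names(params), names(formals(constructor)))
  do.call(constructor, params[known])
}

load_sequence_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.h5$", full.names = TRUE))
  if (!length(files)) stop("data error: no .h5 sequences in ", dir)
  lapply(files, load_tvi)
}

#' Run the end-to-end pipeline from a config file
#'
#' Executes the requested stages (simulate, surrogate, preprocess, train,
#' translate, evaluate, simmap) in dependency order, logging a manifest with
#' per-stage inputs, outputs, seed, config hash, wall time and package
#' version. Re-running with the same config and seed reproduces outputs
#' bit-exactly in single precision.
#'
#' @param config_path path to a YAML config. Top-level keys: `seed`,
#'   `out_dir`, `stages` (character vector), plus one section per stage with
#'   that stage's parameters (see the pipeline vignette for the schema).
#' @return a `pipeline_manifest` list (invisibly); also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config_path) {
  if (!file.exists(config_path)) stop("config error: no such file ", config_path)
  cfgy <- yaml::read_yaml(config_path)
  if (is.null(cfgy$out_dir)) stop("config error: `out_dir` missing")
  out_dir <- cfgy$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfgy$seed %||% 1L
  stages <- cfgy$stages %||% character(0)
  cfg_hash <- unname(tools::md5sum(config_path))
  manifest <- list(config = config_path, config_hash = cfg_hash,
                   seed = seed,
                   package_version = as.character(packageVersion("tvigan")),
                   stages = list())
  record <- function(stage, inputs, outputs, t0) {
    manifest$stages[[stage]] <<- list(
      inputs = inputs, outputs = outputs, seed = seed,
      config_hash = cfg_hash,
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3))
  }
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    tvi_log("stage ", stage, " started")
    res <- tryCatch(fn(t0), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    tvi_log("stage ", stage, " done")
    res
  }
  known <- c("simulate", "surrogate", "preprocess", "train", "translate",
             "evaluate", "simmap")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("config error: unknown stage(s) ",
                        paste(bad, collapse = ", "))
  for (stage in known[known %in% stages]) {
    p <- cfgy[[stage]] %||% list()
    switch(stage,
      simulate = run_stage("simulate", function(t0) {
        dir <- file.path(out_dir, "sim")
        cfg <- cfg_from_params(sim_config, p)
        paths <- simulate_dataset(p$n %||% 8, cfg,
                                  seed = derive_seed(seed, 11), out_dir = dir)
        record("simulate", list(), as.list(paths), t0)
      }),
      surrogate = run_stage("surrogate", function(t0) {
        dir <- file.path(out_dir, "surrogate")
        cfg <- cfg_from_params(surrogate_config, p)
        paths <- surrogate_dataset(p$n %||% 8, cfg,
                                   seed = derive_seed(seed, 23), out_dir = dir)
        record("surrogate", list(), as.list(paths), t0)
      }),
      preprocess = run_stage("preprocess", function(t0) {
        if (is.null(p$in_dir))
          stop("dependency error: preprocess needs `in_dir` (producer: ",
               "an acquisition or surrogate stage)")
        cfg <- cfg_from_params(preprocess_config, p)
        dir <- file.path(out_dir, "preprocessed")
        if (!dir.exists(dir)) dir.create(dir)
        ins <- list.files(p$in_dir, pattern = "\\.h5$", full.names = TRUE)
        if (!length(ins)) stop("dependency error: no sequences in ", p$in_dir)
        outs <- character(length(ins))
        for (i in seq_along(ins)) {
          s <- preprocess_experimental(load_tvi(ins[i]), cfg)
          outs[i] <- file.path(dir, basename(ins[i]))
          save_tvi(s, outs[i], overwrite = TRUE)
        }
        record("preprocess", as.list(ins), as.list(outs), t0)
      }),
      train = run_stage("train", function(t0) {
        dir_a <- p$domain_a %||% file.path(out_dir, "sim")
        dir_b <- p$domain_b %||% file.path(out_dir, "surrogate")
        if (!dir.exists(dir_a))
          stop("dependency error: missing domain-A data at ", dir_a,
               " (producer stage: simulate)")
        if (!dir.exists(dir_b))
          stop("dependency error: missing domain-B data at ", dir_b,
               " (producer stage: surrogate or preprocess)")
        A <- load_sequence_dir(dir_a)
        B <- load_sequence_dir(dir_b)
        cfg <- cfg_from_params(gan_config, p)
        model <- train_translator(A, B, cfg, seed = derive_seed(seed, 37),
                                  n_iter = p$n_iter)
        mp <- file.path(out_dir, "model.rds")
        save_translator(model, mp)
        hp <- file.path(out_dir, "history.csv")
        utils::write.csv(model$history, hp, row.names = FALSE)
        record("train", list(dir_a, dir_b), list(mp, hp), t0)
      }),
      translate = run_stage("translate", function(t0) {
        mp <- p$model %||% file.path(out_dir, "model.rds")
        if (!file.exists(mp))
          stop("dependency error: missing model at ", mp,
               " (producer stage: train)")
        model <- load_translator(mp)
        in_dir <- p$in_dir %||% file.path(out_dir, "sim")
        ins <- list.files(in_dir, pattern = "\\.h5$", full.names = TRUE)
        dir <- file.path(out_dir, "translated")
        if (!dir.exists(dir)) dir.create(dir)
        outs <- character(length(ins))
        for (i in seq_along(ins)) {
          s <- translate(model, load_tvi(ins[i]),
                         direction = p$direction %||% "AtoB",
                         stochastic_seed = derive_seed(seed, 41L + i))
          outs[i] <- file.path(dir, basename(ins[i]))
          save_tvi(s, outs[i], overwrite = TRUE)
        }
        record("translate", as.list(ins), as.list(outs), t0)
      }),
      evaluate = run_stage("evaluate", function(t0) {
        dx <- p$x %||% file.path(out_dir, "translated")
        dy <- p$y %||% file.path(out_dir, "surrogate")
        X <- load_sequence_dir(dx); Y <- load_sequence_dir(dy)
        rep_ <- cross_compare(X, Y, paired = isTRUE(p$paired))
        rp <- file.path(out_dir, "report.json")
        jsonlite::write_json(lapply(rep_, as.list), rp, auto_unbox = TRUE,
                             digits = NA)
        record("evaluate", list(dx, dy), list(rp), t0)
      }),
      simmap = run_stage("simmap", function(t0) {
        din <- p$input %||% file.path(out_dir, "sim")
        dtr <- p$translated %||% file.path(out_dir, "translated")
        X <- load_sequence_dir(din); Y <- load_sequence_dir(dtr)
        if (length(X) != length(Y))
          stop("dependency error: input/translated sets differ in size")
        maps <- mapply(similarity_map, X, Y, SIMPLIFY = FALSE)
        avg <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
        prof <- depth_profile(avg, pixel_pitch_mm = X[[1]]$pixel_pitch_mm)
        pp <- file.path(out_dir, "depth_profile.csv")
        utils::write.csv(prof, pp, row.names = FALSE)
        mp <- file.path(out_dir, "similarity_map.csv")
        utils::write.table(avg, mp, sep = ",", row.names = FALSE,
                           col.names = FALSE)
        record("simmap", list(din, dtr), list(mp, pp), t0)
      }))
  }
  class(manifest) <- "pipeline_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
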