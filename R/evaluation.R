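#' Random cross-validation folds
#'
#' Randomly partitions ids into `n_folds` nearly equally sized folds
#' (sizes differ by at most 1), deterministically for a given seed.
#'
#' @param ids character vector of target individuals.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return Named integer vector of fold numbers (1..n_folds) per id.
#' @export
make_cv_folds <- function(ids, n_folds = 5, seed = 1) {
  n <- length(ids)
  if (n_folds > n) stop("more folds than individuals")
  set.seed(seed)
  fold <- rep(seq_len(n_folds), length.out = n)
  setNames(fold[order(sample.int(n))], ids)
}

#' Define a reference-combination scenario
#'
#' The three scenario modes of a multi-line reference study:
#' `combined_all` (every line joins the reference), `two_predict_third`
#' (the two other lines predict the target) and `within` (the target line
#' predicts itself by cross-validation).
#'
#' @param mode one of `combined_all`, `two_predict_third`, `within`.
#' @param target target line label.
#' @param reference reference line labels (defaults: all lines for
#'   `combined_all`, the non-target lines for `two_predict_third`, the
#'   target for `within`).
#' @param include_target_training_folds for `two_predict_third` only:
#'   whether the target line's non-validation folds also join the
#'   reference (default `FALSE`, the literal two-populations-only
#'   reading).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(mode = c("combined_all", "two_predict_third",
                                   "within"),
                          target,
                          reference = NULL,
                          include_target_training_folds = FALSE) {
  mode <- match.arg(mode)
  all_lines <- c("small", "medium", "large")
  if (!target %in% all_lines) stop("unknown target line: ", target)
  if (is.null(reference)) {
    reference <- switch(mode,
                        combined_all = all_lines,
                        two_predict_third = setdiff(all_lines, target),
                        within = target)
  }
  if (mode == "two_predict_third" && target %in% reference) {
    stop("two_predict_third requires the target outside the reference")
  }
  if (mode == "within" && !identical(reference, target)) {
    stop("within requires reference == target")
  }
  structure(list(mode = mode, target = target, reference = reference,
                 include_target_training_folds =
                   include_target_training_folds),
            class = "scenario_spec")
}

#' The full scenario grid: three modes for each of the three lines
#'
#' @param include_target_training_folds passed to [scenario_spec()] for
#'   the `two_predict_third` scenarios.
#' @return List of nine `scenario_spec`s.
#' @export
default_scenarios <- function(include_target_training_folds = FALSE) {
  out <- list()
  for (target in c("small", "medium", "large")) {
    for (mode in c("combined_all", "two_predict_third", "within")) {
      out[[length(out) + 1L]] <- scenario_spec(
        mode, target,
        include_target_training_folds = include_target_training_folds)
    }
  }
  out
}

#' Training/validation split for one scenario and fold
#'
#' Validation is fold `k` of the target line. Training is, by mode:
#' all other genotyped individuals plus the target's remaining folds
#' (`combined_all`); the reference lines only, with the target's
#' remaining folds excluded unless `include_target_training_folds`
#' (`two_predict_third`); or the target's remaining folds only
#' (`within`).
#'
#' @param spec a [scenario_spec()].
#' @param fold_assignment named fold vector from [make_cv_folds()] over
#'   the target line.
#' @param k validation fold number.
#' @param lines named character vector id -> line over all genotyped
#'   individuals.
#' @return List with `train_ids` and `val_ids`.
#' @export
assemble_scenario <- function(spec, fold_assignment, k, lines) {
  target_ids <- names(fold_assignment)
  val_ids <- target_ids[fold_assignment == k]
  other_folds <- setdiff(target_ids, val_ids)
  ref_ids <- names(lines)[lines %in% setdiff(spec$reference, spec$target)]
  train_ids <- switch(spec$mode,
    within = other_folds,
    combined_all = c(ref_ids, other_folds),
    two_predict_third = if (spec$include_target_training_folds)
      c(ref_ids, other_folds) else ref_ids)
  if (!length(train_ids)) stop("empty training set")
  list(train_ids = train_ids, val_ids = val_ids)
}

#' Predictive accuracy of GEBVs
#'
#' Pearson correlation between GEBVs and the corrected phenotypes of the
#' validation individuals. Optionally divided by `sqrt(h2)` to approximate
#' the correlation with true breeding values.
#'
#' @param gebv named GEBV vector.
#' @param phenotypes corrected phenotypes, same order (or named).
#' @param h2 optional heritability for the `sqrt(h2)` scaling (default
#'   `NULL` = raw correlation).
#' @return Correlation in `[-1, 1]`, or `NA` when either vector is
#'   degenerate or shorter than 3.
#' @export
accuracy <- function(gebv, phenotypes, h2 = NULL) {
  if (!is.null(names(gebv)) && !is.null(names(phenotypes))) {
    phenotypes <- phenotypes[names(gebv)]
  }
  ok <- is.finite(gebv) & is.finite(phenotypes)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(gebv[ok]) == 0 || sd(phenotypes[ok]) == 0) return(NA_real_)
  r <- cor(gebv[ok], phenotypes[ok])
  if (!is.null(h2)) r <- r / sqrt(h2)
  r
}

#' Assemble an analysis-ready study
#'
#' Applies the standard pipeline head: 100 kg endpoint correction,
#' per-line QC, SNP-set intersection across lines, and mean imputation.
#'
#' @param geno raw [geno_matrix()] of the genotyped animals.
#' @param phenotypes `pheno_table` of raw measurements (may cover
#'   additional non-genotyped pedigree animals).
#' @param pedigree a `pedigree_table` (used by ssGBLUP; may be `NULL` if
#'   ssGBLUP is not evaluated).
#' @param thresholds a [qc_thresholds()].
#' @return A list of class `gp_study`: `geno` (combined, imputed),
#'   `pheno` (with `age100`, `bf100`), `pedigree`, `lines` (named vector
#'   over genotyped ids), `qc_report`.
#' @export
prepare_study <- function(geno, phenotypes, pedigree = NULL,
                          thresholds = qc_thresholds()) {
  pheno <- apply_corrections(phenotypes)
  ids <- rownames(geno$dosages)
  missing_ph <- setdiff(ids, pheno$id)
  if (length(missing_ph)) {
    stop("genotyped individuals without phenotype records: ",
         paste(head(missing_ph, 5), collapse = ", "))
  }
  lines <- setNames(pheno$line, pheno$id)[ids]
  qc <- apply_qc(geno, thresholds, lines)
  combined <- intersect_snp_sets(qc$per_line)
  combined <- mean_impute(combined)
  lines <- lines[rownames(combined$dosages)]
  structure(list(geno = combined, pheno = pheno, pedigree = pedigree,
                 lines = lines, qc_report = qc$report),
            class = "gp_study")
}

# ancestors-first closure of a set of individuals within a pedigree
restrict_pedigree <- function(pedigree, ids) {
  idx <- setNames(seq_len(nrow(pedigree)), pedigree$id)
  keep <- rep(FALSE, nrow(pedigree))
  keep[idx[intersect(ids, pedigree$id)]] <- TRUE
  for (i in rev(seq_len(nrow(pedigree)))) {
    if (keep[i]) {
      for (par in c(pedigree$sire[i], pedigree$dam[i])) {
        if (!is.na(par)) keep[idx[[par]]] <- TRUE
      }
    }
  }
  out <- pedigree[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

model_seed <- function(base, scenario_i, repeat_i, fold_k, model_i) {
  as.integer((base + 7919 * repeat_i + 613 * fold_k + 131 * model_i +
                17 * scenario_i) %% 2147483647)
}

fit_and_predict <- function(model, trait, train_ids, val_ids, study,
                            mcmc, reml, blend_weight, seed) {
  pheno <- study$pheno
  y_all <- setNames(pheno[[trait]], pheno$id)
  sex_all <- setNames(pheno$sex, pheno$id)
  analysis_ids <- c(train_ids, val_ids)

  if (model %in% c("bayesA", "bayesB", "bayesC")) {
    M_train <- study$geno$dosages[train_ids, , drop = FALSE]
    X <- fixed_effects_design(sex_all[train_ids])
    settings <- mcmc
    settings$seed <- seed
    fit <- switch(model,
                  bayesA = fit_bayesA(y_all[train_ids], X, M_train, settings),
                  bayesB = fit_bayesB(y_all[train_ids], X, M_train, settings),
                  bayesC = fit_bayesC(y_all[train_ids], X, M_train, settings))
    predict_validation(fit, study$geno$dosages[val_ids, , drop = FALSE])
  } else if (model == "gblup") {
    sub <- subset_geno(study$geno, individuals = analysis_ids)
    G <- compute_G(sub)
    y <- y_all[analysis_ids]
    y[val_ids] <- NA
    X <- fixed_effects_design(sex_all[analysis_ids])
    fit <- fit_gblup(y, X, G, max_iter = reml$max_iter, tol = reml$tol)
    fit$gebv[val_ids]
  } else if (model == "ssgblup") {
    if (is.null(study$pedigree)) stop("ssGBLUP requires a pedigree")
    ped <- restrict_pedigree(study$pedigree, analysis_ids)
    A <- compute_A(ped)
    genotyped <- intersect(ped$id, analysis_ids)
    sub <- subset_geno(study$geno, individuals = genotyped)
    G <- compute_G(sub)
    A22 <- extract_A22(A, genotyped)
    Gb <- tune_and_blend_G(G, A22, blend_weight = blend_weight)
    Hinv <- compute_H_inverse(A, A22, Gb, genotyped)
    y <- y_all[ped$id]
    names(y) <- ped$id
    y[intersect(val_ids, ped$id)] <- NA
    sex_ped <- sex_all[ped$id]
    # pedigree members without phenotype records stay unphenotyped
    if (anyNA(sex_ped)) sex_ped[is.na(sex_ped)] <- "female"
    X <- fixed_effects_design(sex_ped)
    fit <- fit_ssgblup(y, X, Hinv, max_iter = reml$max_iter, tol = reml$tol)
    fit$gebv[val_ids]
  } else {
    stop("unknown model: ", model)
  }
}

#' Repeated k-fold cross-validation over scenarios, models and traits
#'
#' Runs the full evaluation grid: for every scenario, trait and repeat,
#' the target line is split into `n_folds` folds; each fold in turn is
#' the validation set (phenotypes masked), the model is trained on the
#' scenario's reference composition, and accuracy is the correlation
#' between predicted GEBVs and the corrected phenotypes of the validation
#' animals. Model failures are recorded per cell and the run continues.
#'
#' @param study a `gp_study` from [prepare_study()].
#' @param scenarios list of [scenario_spec()]s (default: the nine-cell
#'   grid of [default_scenarios()]).
#' @param models character subset of
#'   `c("bayesA", "bayesB", "bayesC", "gblup", "ssgblup")`.
#' @param traits character subset of `c("age100", "bf100")`.
#' @param n_repeats,n_folds cross-validation plan (defaults 20 x 5).
#' @param seed master seed; per-repeat fold seeds and per-fit sampler
#'   seeds are derived from it by fixed offsets.
#' @param mcmc an [mcmc_settings()] used for the Bayesian models.
#' @param reml list with `max_iter` and `tol` for the REML-based models.
#' @param blend_weight ssGBLUP G-blending weight.
#' @return A data.frame of class `cv_result`: one row per (scenario,
#'   trait, model, repeat, fold) with accuracy, training/validation sizes
#'   and an error note for failed cells.
#' @export
run_repeated_cv <- function(study, scenarios = default_scenarios(),
                            models = c("bayesA", "bayesB", "bayesC",
                                       "gblup", "ssgblup"),
                            traits = c("age100", "bf100"),
                            n_repeats = 20, n_folds = 5, seed = 1,
                            mcmc = mcmc_settings(),
                            reml = list(max_iter = 200, tol = 1e-6),
                            blend_weight = 0.05) {
  stopifnot(inherits(study, "gp_study"))
  rows <- list()
  for (si in seq_along(scenarios)) {
    spec <- scenarios[[si]]
    target_ids <- names(study$lines)[study$lines == spec$target]
    if (length(target_ids) < n_folds) {
      stop("target line ", spec$target, " smaller than n_folds")
    }
    for (r in seq_len(n_repeats)) {
      folds <- make_cv_folds(target_ids, n_folds,
                             seed = (seed + 1009L * r + 31L * si) %%
                               2147483647L)
      for (k in seq_len(n_folds)) {
        split <- assemble_scenario(spec, folds, k, study$lines)
        for (trait in traits) {
          for (mi in seq_along(models)) {
            model <- models[mi]
            note <- ""
            acc <- tryCatch({
              gebv <- fit_and_predict(
                model, trait, split$train_ids, split$val_ids, study,
                mcmc, reml, blend_weight,
                seed = model_seed(seed, si, r, k, mi))
              ph <- setNames(study$pheno[[trait]], study$pheno$id)
              accuracy(gebv, ph[split$val_ids])
            }, error = function(e) {
              note <<- conditionMessage(e)
              NA_real_
            })
            rows[[length(rows) + 1L]] <- data.frame(
              scenario = spec$mode, target = spec$target, trait = trait,
              model = model, rep = r, fold = k,
              n_train = length(split$train_ids),
              n_val = length(split$val_ids),
              accuracy = acc, note = note, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Summarise cross-validation results as publication-style tables
#'
#' One table per (target line, trait): rows are scenarios, columns the
#' five models; each cell is the mean over repeats of the per-repeat fold
#' means. Missing cells are `NA`.
#'
#' @param results a `cv_result` from [run_repeated_cv()].
#' @return A named list of class `cv_summary` (one data.frame per
#'   `target.trait`), each with attribute `sd` holding the between-repeat
#'   standard deviation of the repeat means.
#' @export
summarize_cv <- function(results) {
  results <- as.data.frame(results)
  out <- list()
  targets <- unique(results$target)
  traits <- unique(results$trait)
  models <- unique(results$model)
  for (tg in targets) {
    for (tr in traits) {
      sub <- results[results$target == tg & results$trait == tr, ]
      scens <- unique(sub$scenario)
      tab <- matrix(NA_real_, length(scens), length(models),
                    dimnames = list(scens, models))
      sdtab <- tab
      for (sc in scens) {
        for (md in models) {
          cell <- sub[sub$scenario == sc & sub$model == md, ]
          if (!nrow(cell)) next
          rep_means <- tapply(cell$accuracy, cell$rep,
                              function(x) mean(x, na.rm = TRUE))
          rep_means <- rep_means[is.finite(rep_means)]
          if (length(rep_means)) {
            tab[sc, md] <- mean(rep_means)
            sdtab[sc, md] <- if (length(rep_means) > 1) sd(rep_means) else NA
          }
        }
      }
      df <- as.data.frame(tab)
      attr(df, "sd") <- as.data.frame(sdtab)
      out[[paste(tg, tr, sep = ".")]] <- df
    }
  }
  class(out) <- "cv_summary"
  out
}

#' @export
print.cv_summary <- function(x, digits = 3, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(round(as.matrix(x[[nm]]), digits))
    cat("\n")
  }
  invisible(x)
}
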