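## Experiment drivers: run the full offline/online pipeline on a synthetic
## cohort and tabulate mapping errors, singular-value spectra, reduced-order
## errors and timings.

#' Run the cohort reduced-order-modeling experiment
#'
#' Full pipeline on a synthetic cohort: sample geometries, solve the
#' requested full-order models on every subject, map every non-target
#' solution onto the target geometry (analytic ground-truth deformations or
#' demons registration), then build leave-one-out POD bases and solve the
#' reduced problems for a grid of basis sizes.  Mapping errors, normalized
#' singular values, reduced errors (per field and combined) and timings are
#' returned as data frames.
#'
#' @param spec a [cohort_spec()].
#' @param models subset of `c("A", "B")`.
#' @param d_values basis sizes to evaluate (values exceeding the snapshot
#'   count are dropped per subset).
#' @param targets `"auto"` (first healthy-like and first iNPH-like subject)
#'   or integer subject indices.
#' @param subsets snapshot subsets to compare: any of `"full"`,
#'   `"healthy"`, `"inph"`.
#' @param backend `"analytic"` (ground-truth deformations) or `"demons"`
#'   (in-repo registration of the rasterized images).
#' @param params_a,params_b model parameter lists.
#' @param reg_opts [register_opts()] for the demons backend.
#' @param transfer_opts list with `k_neighbors` and `sigma_factor`.
#' @param keep_fields also return solutions/snapshots/systems (memory
#'   permitting) for downstream reuse.
#' @param verbose print progress lines.
#' @return A list of class `grom_experiment` with data frames `mapping`,
#'   `sigma`, `reduced`, `timing`, and metadata.
#' @export
grom_experiment <- function(spec, models = c("A", "B"),
                            d_values = c(2L, 5L, 10L, 20L, 30L),
                            targets = "auto", subsets = "full",
                            backend = c("analytic", "demons"),
                            params_a = model_a_params(),
                            params_b = model_b_params(),
                            reg_opts = register_opts(),
                            transfer_opts = list(k_neighbors = 8L,
                                                 sigma_factor = 1.0),
                            keep_fields = FALSE, verbose = FALSE) {
  backend <- match.arg(backend)
  models <- match.arg(models, c("A", "B"), several.ok = TRUE)
  stopifnot(all(subsets %in% c("full", "healthy", "inph")))
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- sample_cohort(spec)
  n <- length(cohort)
  groups <- vapply(cohort, function(p) p$group, character(1))
  ids <- vapply(cohort, function(p) p$subject_id, character(1))
  say("cohort: %d subjects (%d healthy-like, %d iNPH-like)", n,
      sum(groups == "healthy"), sum(groups == "inph"))

  meshes <- lapply(cohort, build_mesh, h = spec$mesh_h)
  sols <- list(); systems <- list(); full_times <- list()
  mparams <- list(A = params_a, B = params_b)
  for (mo in models) {
    say("solving model %s full-order on %d subjects ...", mo, n)
    sols[[mo]] <- vector("list", n)
    t_as <- t_so <- numeric(n)
    for (i in seq_len(n)) {
      t0 <- proc.time()[["elapsed"]]
      sys <- if (mo == "A") assemble_model_a(meshes[[i]], params_a)
             else assemble_model_b(meshes[[i]], params_b)
      t_as[i] <- proc.time()[["elapsed"]] - t0
      sol <- solve_full(sys)
      t_so[i] <- sol$time
      sols[[mo]][[i]] <- fem_field(sys$space, meshes[[i]], sol$coeffs,
                                   sys$field_names)
    }
    full_times[[mo]] <- data.frame(model = mo, subject = ids,
                                   assembly = t_as, solve = t_so)
  }

  if (identical(targets, "auto")) {
    targets <- c(match("healthy", groups), match("inph", groups))
    targets <- targets[!is.na(targets)]
  }
  targets <- as.integer(targets)

  mapping_rows <- list(); sigma_rows <- list(); reduced_rows <- list()
  timing_rows <- list()
  kept <- if (keep_fields) list() else NULL

  for (tgt in targets) {
    say("target %s (%s), backend %s", ids[tgt], groups[tgt], backend)
    mapped <- list(); for (mo in models) mapped[[mo]] <- list()
    src_idx <- setdiff(seq_len(n), tgt)
    img_tgt <- if (backend == "demons") rasterize(cohort[[tgt]], spec)
    for (i in src_idx) {
      def <- if (backend == "analytic") {
        analytic_deformation(cohort[[i]], cohort[[tgt]])
      } else {
        register(moving = img_tgt, fixed = rasterize(cohort[[i]], spec),
                 opts = reg_opts)
      }
      dm <- deform_mesh(meshes[[i]], def)
      for (mo in models) {
        src <- sols[[mo]][[i]]
        sf <- fem_field(build_space(dm, src$space$order, src$space$n_fields),
                        dm, src$coeffs, src$field_names)
        tr <- transfer_field(sf, meshes[[tgt]],
                             k_neighbors = transfer_opts$k_neighbors,
                             sigma_factor = transfer_opts$sigma_factor)
        mapped[[mo]][[as.character(i)]] <- tr$field
        err <- mapping_error(tr$field, sols[[mo]][[tgt]])
        mapping_rows[[length(mapping_rows) + 1L]] <- data.frame(
          target = ids[tgt], target_group = groups[tgt], source = ids[i],
          source_group = groups[i], model = mo,
          field = names(err), error = as.numeric(err),
          n_extrapolated = tr$report$n_extrapolated)
      }
    }
    for (mo in models) {
      t0 <- proc.time()[["elapsed"]]
      sys_t <- if (mo == "A") assemble_model_a(meshes[[tgt]], params_a)
               else assemble_model_b(meshes[[tgt]], params_b)
      t_assembly <- proc.time()[["elapsed"]] - t0
      ref <- sols[[mo]][[tgt]]
      full_solve <- full_times[[mo]]$solve[tgt]
      for (sub in subsets) {
        sel <- switch(sub,
                      full = src_idx,
                      healthy = src_idx[groups[src_idx] == "healthy"],
                      inph = src_idx[groups[src_idx] == "inph"])
        if (length(sel) < 1) next
        snaps <- build_snapshots(mapped[[mo]][as.character(sel)],
                                 source_ids = ids[sel])
        sv <- svd(snaps$X, nu = 0, nv = 0)$d
        sigma_rows[[length(sigma_rows) + 1L]] <- data.frame(
          target = ids[tgt], target_group = groups[tgt], model = mo,
          subset = sub, index = seq_along(sv), sigma = sv,
          sigma_norm = sv / sv[1])
        for (d in unique(pmin(d_values, ncol(snaps$X)))) {
          rg <- run_grom(sys_t, snaps, d, reference = ref)
          comb <- relative_l2(rg$field, ref)
          reduced_rows[[length(reduced_rows) + 1L]] <- data.frame(
            target = ids[tgt], target_group = groups[tgt], model = mo,
            subset = sub, d = d,
            field = c(names(rg$errors), "combined"),
            error = c(as.numeric(rg$errors), comb))
          timing_rows[[length(timing_rows) + 1L]] <- data.frame(
            target = ids[tgt], model = mo, subset = sub, d = d,
            full_assembly = t_assembly, full_solve = full_solve,
            projection = rg$timings[["projection"]],
            reduced_solve = rg$timings[["reduced_solve"]],
            speedup = full_solve / max(rg$timings[["reduced_solve"]], 1e-9))
          if (keep_fields && sub == "full") {
            kept$reduced[[paste(ids[tgt], mo, d, sep = "/")]] <- rg$field
          }
        }
        if (keep_fields && sub == "full") {
          kept$snapshots[[paste(ids[tgt], mo, sep = "/")]] <- snaps
        }
      }
    }
  }
  out <- list(mapping = do.call(rbind, mapping_rows),
              sigma = do.call(rbind, sigma_rows),
              reduced = do.call(rbind, reduced_rows),
              timing = do.call(rbind, timing_rows),
              full_times = do.call(rbind, full_times),
              cohort = cohort, targets = targets, groups = groups, ids = ids,
              spec = spec, backend = backend, models = models)
  if (keep_fields) {
    out$solutions <- sols
    out$meshes <- meshes
    out$kept <- kept
  }
  class(out) <- "grom_experiment"
  out
}

#' @export
print.grom_experiment <- function(x, ...) {
  cat(sprintf("<grom_experiment: %d subjects, models %s, backend %s>\n",
              length(x$cohort), paste(x$models, collapse = "+"), x$backend))
  if (!is.null(x$reduced)) {
    agg <- stats::aggregate(error ~ model + d, data = x$reduced, FUN = stats::median)
    print(agg)
  }
  invisible(x)
}

#' Subgroup summary of mapping errors
#'
#' Medians and quartiles of the per-field mapping error by target, model and
#' source subgroup (full cohort, healthy-only sources, iNPH-only sources).
#'
#' @param experiment a [grom_experiment()] result.
#' @return A data frame with one row per (target, model, field, subset).
#' @export
experiment_mapping_error <- function(experiment) {
  mp <- experiment$mapping
  rows <- list()
  for (tgt in unique(mp$target)) for (mo in unique(mp$model)) {
    sub <- mp[mp$target == tgt & mp$model == mo, ]
    for (fl in unique(sub$field)) {
      fsub <- sub[sub$field == fl, ]
      for (ss in c("full", "healthy", "inph")) {
        e <- if (ss == "full") fsub$error else fsub$error[fsub$source_group == ss]
        if (!length(e)) next
        q <- stats::quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tgt, model = mo, field = fl, subset = ss,
          n_sources = length(e), q1 = q[1], median = q[2], q3 = q[3])
      }
    }
  }
  do.call(rbind, rows)
}

#' Singular-value spectra and reduced errors by snapshot subset
#'
#' @param experiment a [grom_experiment()] result (run with the subsets of
#'   interest).
#' @return A list with `sigma` (normalized spectra) and `reduced`
#'   (error-vs-d table).
#' @export
experiment_svd_and_reduction <- function(experiment) {
  list(sigma = experiment$sigma, reduced = experiment$reduced)
}

#' Timing table of the reduced-order pipeline
#'
#' Wall times for full assembly, projection overhead, full solve and
#' reduced solve at each basis size, with the solve-time ratio.  Reported,
#' never asserted: timings are hardware-dependent.
#'
#' @param experiment a [grom_experiment()] result.
#' @return The timing data frame.
#' @export
experiment_timing <- function(experiment) experiment$timing
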