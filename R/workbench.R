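# Study orchestration: fixture access, colorized visualization export,
# configuration and reporting.

#' Load the packaged per-scan mean surface-distance tables
#'
#' Per-scan signed surface-distance summaries (mean, sd and the
#' mean +/- 1.96 sd interval, mm) for paired weight-bearing cone-beam and
#' multidetector CT knee bone models: 4 patient scans, 10 single-leg
#' cadaver scans and 10 bilateral-leg cadaver scans, four bones each.
#' These per-scan values derive from real scans and are shipped as a
#' fixture; everything downstream (group summaries, normality, TOST) is
#' recomputed from them.
#'
#' @param path optional CSV path; defaults to the packaged fixture.
#' @param validate verify row counts and column checksums.
#' @return data.frame with columns `dataset`, `subject`, `bone`,
#'   `mean_mm`, `sd_mm`, `upper_mm`, `lower_mm`.
#' @export
load_fixture_tables <- function(path = NULL, validate = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "knee_mean_distances.csv",
                        package = "bonequiv", mustWork = TRUE)
  fx <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("dataset", "subject", "bone", "mean_mm", "sd_mm", "upper_mm",
            "lower_mm")
  if (!all(need %in% names(fx))) stop("fixture is missing required columns")
  if (validate) {
    counts <- table(fx$dataset)
    ok <- identical(nrow(fx), 96L) &&
      counts[["patient"]] == 16L && counts[["cadaver_single"]] == 40L &&
      counts[["cadaver_bilateral"]] == 40L &&
      abs(sum(fx$mean_mm) - (-6.899)) < 1e-9 &&
      abs(sum(fx$sd_mm) - 44.08) < 1e-9
    if (!ok) stop("corrupt fixture: checksum mismatch")
  }
  fx
}

#' Per-scan means of a comparison group
#'
#' The two published comparison groups pool the 16 patient values with the
#' 40 values of one cadaver setup, 56 samples each.
#'
#' @param fixture data.frame from [load_fixture_tables()].
#' @param group `"patient+single"` or `"patient+bilateral"`.
#' @return numeric vector of per-scan mean distances (mm).
#' @export
fixture_group_means <- function(fixture, group = c("patient+single",
                                                   "patient+bilateral")) {
  group <- match.arg(group)
  sets <- c("patient", if (group == "patient+single") "cadaver_single"
            else "cadaver_bilateral")
  fixture$mean_mm[fixture$dataset %in% sets]
}

#' Map signed distances to diverging colors
#'
#' Symmetric diverging palette: saturated blue at `-range` (reference model
#' larger), a light midpoint at zero, saturated red at `+range` (source
#' model larger); values beyond the range are clamped to the end colors.
#' The map is odd-symmetric: `color(d)` equals `color(-d)` with the red and
#' blue channels exchanged.
#'
#' @param distances numeric vector or `distance_result` (mm).
#' @param range symmetric color range r in mm (default 1.0).
#' @return n x 3 integer matrix of RGB values in 0-255.
#' @export
colorize_distances <- function(distances, range = 1.0) {
  if (range <= 0) stop("range must be > 0")
  d <- if (inherits(distances, "distance_result")) distances$distance
       else as.numeric(distances)
  na <- !is.finite(d)
  u <- pmin(pmax(d / range, -1), 1)
  u[na] <- 0
  lo <- c(0, 0, 180)      # -range: dark blue
  mid <- c(245, 245, 245) # 0: light
  hi <- c(180, 0, 0)      # +range: dark red
  out <- matrix(0L, length(u), 3)
  neg <- u < 0
  for (ch in 1:3) {
    v <- numeric(length(u))
    v[neg] <- mid[ch] + (lo[ch] - mid[ch]) * (-u[neg])
    v[!neg] <- mid[ch] + (hi[ch] - mid[ch]) * u[!neg]
    out[, ch] <- as.integer(round(v))
  }
  out[na, ] <- NA_integer_
  out
}

#' Study configuration
#'
#' @param phantom list of [phantom_spec] (phantom mode), or NULL.
#' @param roster data.frame with columns `subject`, `bone`, `path_a`,
#'   `path_b` of mask files (file mode), or NULL.
#' @param fixture_only if TRUE, skip geometry and run the statistics layer
#'   on the packaged fixture.
#' @param fixture_path optional CSV of per-scan means used instead of the
#'   packaged fixture in fixture-only mode (validation is skipped).
#' @param compare a [compare_config()].
#' @param margin,alpha TOST settings.
#' @param color_range color map range (mm).
#' @param seed study seed.
#' @return a `study_config` object.
#' @export
study_config <- function(phantom = NULL, roster = NULL, fixture_only = FALSE,
                         fixture_path = NULL, compare = compare_config(),
                         margin = 0.15, alpha = 0.05, color_range = 1.0,
                         seed = 1L) {
  if (margin <= 0) stop("margin must be > 0")
  if (!fixture_only && is.null(phantom) && is.null(roster))
    stop("provide phantom specs, a file roster, or fixture_only = TRUE")
  structure(list(phantom = phantom, roster = roster,
                 fixture_only = fixture_only, fixture_path = fixture_path,
                 compare = compare,
                 margin = margin, alpha = alpha, color_range = color_range,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from YAML
#'
#' Phantom-mode settings under `phantom:` (subjects, bones, delta, noise,
#' scale, seed); `margin`, `alpha`, `color_range` at the top level.
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- NULL
  if (!is.null(y$phantom)) {
    p <- y$phantom
    specs <- knee_study_specs(
      n_subjects = p$subjects %||% 4L,
      bones = p$bones %||% PHANTOM_BONES,
      delta = p$delta %||% 0,
      sigma_noise = p$noise %||% 0.1,
      scale = p$scale %||% 1,
      seed = p$seed %||% y$seed %||% 1L)
  }
  study_config(phantom = specs,
               fixture_only = isTRUE(y$fixture_only),
               margin = y$margin %||% 0.15, alpha = y$alpha %||% 0.05,
               color_range = y$color_range %||% 1.0,
               seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

study_stats_tables <- function(means_tbl, margin, alpha) {
  groups <- list()
  if (all(c("patient", "cadaver_single") %in% means_tbl$dataset)) {
    groups[["patient+single"]] <-
      means_tbl$mean_mm[means_tbl$dataset %in% c("patient", "cadaver_single")]
    groups[["patient+bilateral"]] <-
      means_tbl$mean_mm[means_tbl$dataset %in% c("patient", "cadaver_bilateral")]
  } else {
    groups[["all"]] <- means_tbl$mean_mm
  }
  summary_tbl <- do.call(rbind, lapply(split(means_tbl, means_tbl[c("dataset", "bone")], drop = TRUE),
    function(g) {
      s <- if (nrow(g) >= 2) aggregate_group(g$mean_mm, label = g$bone[1])
      else data.frame(bone = g$bone[1], n = 1L, mean = g$mean_mm, sd = NA_real_,
                      lower = NA_real_, upper = NA_real_,
                      mean_fmt = fmt_mm(g$mean_mm), sd_fmt = NA_character_,
                      lower_fmt = NA_character_, upper_fmt = NA_character_)
      cbind(dataset = g$dataset[1], s)
    }))
  rownames(summary_tbl) <- NULL
  norm_tbl <- do.call(rbind, lapply(names(groups), function(nm) {
    x <- groups[[nm]]
    sw <- shapiro_wilk(x)
    ks <- ks_normal(x)
    data.frame(group = nm, n = length(x), shapiro_W = sw$W, shapiro_p = sw$p,
               ks_D = ks$D, ks_p = ks$p,
               normal = sw$p > 0.05 && ks$p > 0.05)
  }))
  tost_tbl <- do.call(rbind, lapply(names(groups), function(nm) {
    r <- tost_one_sample(groups[[nm]], margin = margin, alpha = alpha)
    data.frame(group = nm, n = r$n, mean = r$mean, margin = r$margin,
               p_lower = r$p_lower, p_upper = r$p_upper,
               ci_lower = r$ci_lower, ci_upper = r$ci_upper,
               equivalent = r$equivalent)
  }))
  qq <- lapply(groups, qq_points)
  list(summary = summary_tbl, normality = norm_tbl, tost = tost_tbl, qq = qq)
}

#' Run a full study
#'
#' Phantom mode: generates every subject x bone pair, runs
#' [compare_bone_pair()] on each (failures are recorded and the study
#' continues), then aggregates per-bone means, tests normality and runs
#' TOST on the pooled per-bone means. Fixture-only mode skips the geometry
#' and reproduces the published statistics layer from the packaged
#' per-scan means.
#'
#' @param config a [study_config()].
#' @return a `study_report`: list with `pairs` (per-pair results),
#'   `means` (per-pair mean table), `stats` (summary/normality/TOST
#'   tables), `failures`, `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (config$fixture_only) {
    fx <- load_fixture_tables(config$fixture_path,
                              validate = is.null(config$fixture_path))
    stats <- study_stats_tables(fx, config$margin, config$alpha)
    return(structure(list(pairs = list(), means = fx, stats = stats,
                          failures = list(), config = config),
                     class = "study_report"))
  }
  pairs <- list()
  if (!is.null(config$phantom)) {
    for (i in seq_along(config$phantom)) {
      sp <- config$phantom[[i]]
      pr <- tryCatch(generate_bone_pair(sp), error = function(e) e)
      if (inherits(pr, "error")) {
        pairs[[i]] <- list(subject = as.integer(sp$subject %||% i),
                           bone = sp$bone, error = pr)
      } else {
        pairs[[i]] <- list(subject = as.integer(sp$subject %||% i),
                           bone = pr$bone, grid_a = pr$grid_a,
                           grid_b = pr$grid_b, truth = pr$truth)
      }
    }
  } else {
    for (i in seq_len(nrow(config$roster))) {
      row <- config$roster[i, ]
      pairs[[i]] <- list(subject = row$subject, bone = row$bone,
                         grid_a = read_mask_any(row$path_a),
                         grid_b = read_mask_any(row$path_b), truth = NULL)
    }
  }
  results <- vector("list", length(pairs))
  failures <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    res <- if (!is.null(p$error)) p$error
           else tryCatch(compare_bone_pair(p$grid_a, p$grid_b, bone = p$bone,
                                           config = config$compare),
                         error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(index = i, subject = p$subject, bone = p$bone,
             message = conditionMessage(res))
      message("pair ", i, " (", p$bone, ", subject ", p$subject,
              ") failed: ", conditionMessage(res))
      results[[i]] <- NULL
    } else {
      res$subject <- p$subject
      res$bone <- p$bone
      res$truth <- p$truth
      results[[i]] <- res
    }
  }
  ok <- !vapply(results, is.null, TRUE)
  means <- do.call(rbind, lapply(results[ok], function(r)
    data.frame(dataset = "phantom", subject = r$subject, bone = r$bone,
               mean_mm = r$summary$mean, sd_mm = r$summary$sd,
               upper_mm = r$summary$upper, lower_mm = r$summary$lower,
               stringsAsFactors = FALSE)))
  stats <- if (sum(ok) >= 3) study_stats_tables(means, config$margin, config$alpha)
           else NULL
  structure(list(pairs = results[ok], means = means, stats = stats,
                 failures = failures, config = config),
            class = "study_report")
}

read_mask_any <- function(path) {
  if (grepl("\\.mha$", path)) read_mha_mask(path) else read_nifti_mask(path)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(x$pairs), " bone pairs, ",
      length(x$failures), " failures\n", sep = "")
  if (!is.null(x$stats)) {
    cat("TOST (margin +/-", format(x$config$margin), " mm):\n", sep = "")
    print(x$stats$tost, row.names = FALSE)
  }
  invisible(x)
}

#' Write all study artifacts to a directory
#'
#' CSV + JSON twins of the summary, normality and TOST tables, Q-Q point
#' tables, per-pair colorized PLY meshes (signed distance scalar + RGB),
#' transform JSON files, and a run manifest (settings, seed, package
#' version).
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name) {
    write.csv(obj, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    jsonlite::write_json(obj, file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(report$means) && nrow(report$means) > 0) wr(report$means, "per_scan_means")
  if (!is.null(report$stats)) {
    wr(report$stats$summary, "summary_table")
    wr(report$stats$normality, "normality_table")
    wr(report$stats$tost, "tost_table")
    for (nm in names(report$stats$qq)) {
      q <- report$stats$qq[[nm]]
      write.csv(data.frame(theoretical = q$theoretical, sample = q$sample),
                file.path(dir, paste0("qq_", gsub("[^a-z]+", "_", nm), ".csv")),
                row.names = FALSE)
    }
  }
  for (r in report$pairs) {
    stem <- sprintf("%s_s%02d", r$bone %||% "bone", as.integer(r$subject %||% 0))
    rgb <- colorize_distances(r$mesh_a$scalar, report$config$color_range)
    rgb[is.na(rgb)] <- 128L
    write_ply(r$mesh_a, file.path(dir, paste0(stem, "_a.ply")),
              scalar = ifelse(is.na(r$mesh_a$scalar), 0, r$mesh_a$scalar),
              rgb = rgb)
    jsonlite::write_json(
      list(rotation = unclass(r$transform$rotation),
           translation = r$transform$translation),
      file.path(dir, paste0(stem, "_transform.json")),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  manifest <- list(package = "bonequiv",
                   version = as.character(utils::packageVersion("bonequiv")),
                   seed = report$config$seed, margin = report$config$margin,
                   alpha = report$config$alpha,
                   n_pairs = length(report$pairs),
                   n_failures = length(report$failures),
                   failures = report$failures,
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
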