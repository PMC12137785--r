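## Full cross-application study: per-session tailored pulses (Config 1..S),
## one universal pulse from a library, one frozen default shim; every
## configuration evaluated on every session of every subject; results
## grouped into the interday / same-operator / interyear studies and fed to
## the CV-space statistics.

#' Default study groupings
#'
#' Session index sets of the three longitudinal studies: same-day scans by
#' different operators (sessions 3 and 4), a 1-year interval with the same
#' operator (sessions 1 and 3), and a 2-year span with three operators
#' (sessions 1, 2 and 4).
#' @return named list of integer vectors.
#' @export
studyGroupings <- function() {
  list(interday = c(3L, 4L), sameOperator = c(1L, 3L),
       interyear = c(1L, 2L, 4L))
}

#' Run the full reproducibility study
#'
#' Generates the test cohort and design library, designs one universal pulse
#' from the full library, one tailored pulse per (subject, session), and the
#' frozen default shim; evaluates every method on every (subject, session);
#' assembles per-grouping CV tables, cluster statistics and pairwise
#' signed-rank tests. Fully reproducible from `masterSeed`.
#'
#' @param masterSeed integer.
#' @param nSubjects,nSessions test cohort layout.
#' @param librarySize number of library map sets for the universal design.
#' @param grid A [GridSpec-class].
#' @param cfg A [DesignConfig-class].
#' @param variability settings from [sessionVariability()].
#' @param groupings named list of session index sets (see
#'   [studyGroupings()]); groupings referencing absent sessions are errors.
#' @return A [StudyResult-class].
#' @export
runStudy <- function(masterSeed = 1L, nSubjects = 6L, nSessions = 4L,
                     librarySize = 22L, grid = defaultGrid(),
                     cfg = DesignConfig(),
                     variability = sessionVariability(),
                     groupings = studyGroupings()) {
  for (g in names(groupings)) {
    bad <- setdiff(groupings[[g]], seq_len(nSessions))
    if (length(bad))
      stop(sprintf("grouping '%s' references absent session(s) %s",
                   g, paste(bad, collapse = ", ")))
  }
  cohort <- generateCohort(nSubjects, nSessions, masterSeed = masterSeed,
                           grid = grid, variability = variability,
                           cohort = "test")
  library <- generateCohort(librarySize, 1L, masterSeed = masterSeed,
                            grid = grid, variability = variability,
                            cohort = "library")
  libEntries <- .libraryEntries(library)
  up <- designUniversal(libEntries, cfg)
  def <- defaultShim(cfg, vendorReference(grid))
  tp <- vector("list", nSubjects)
  for (v in seq_len(nSubjects)) {
    tp[[v]] <- vector("list", nSessions)
    for (s in seq_len(nSessions)) {
      e <- cohortEntry(cohort, v, s)
      tp[[v]][[s]] <- designTailored(e$b1, e$roi, cfg)
    }
  }
  rows <- list()
  k <- 0L
  for (v in seq_len(nSubjects)) {
    for (s in seq_len(nSessions)) {
      e <- cohortEntry(cohort, v, s)
      op <- cohort$manifest$operator[cohort$manifest$subject == v &
                                       cohort$manifest$session == s]
      evalOne <- function(pulse, method, config) {
        fa <- predictFaSta(e$b1, pulse)
        dist <- faDistribution(fa, e$roi)
        rf <- rfMetrics(pulse)
        data.frame(subject = v, session = s, operator = op,
                   method = method, config = config,
                   tsg = identical(config, s),
                   cv = computeCv(fa, e$roi),
                   medianFa = dist$median, q25 = dist$q25, q75 = dist$q75,
                   minFa = dist$min, maxFa = dist$max,
                   peakVoltage = rf@peak, meanPower = rf@meanPower,
                   stringsAsFactors = FALSE)
      }
      k <- k + 1L
      rows[[k]] <- evalOne(def, "default", NA_integer_)
      k <- k + 1L
      rows[[k]] <- evalOne(up, "UP", NA_integer_)
      for (j in seq_len(nSessions)) {
        k <- k + 1L
        rows[[k]] <- evalOne(tp[[v]][[j]], "TP", j)
      }
    }
  }
  cvGrid <- do.call(rbind, rows)
  res <- new("StudyResult", cvGrid = cvGrid, tables = list(),
             summaries = data.frame(), tests = list(),
             pulses = list(default = def, up = up, tp = tp),
             groupings = groupings, seed = as.integer(masterSeed),
             meta = list(nSubjects = nSubjects, nSessions = nSessions,
                         librarySize = librarySize,
                         variability = variability))
  groupStudies(res)
}

#' Group the cross-application results into the longitudinal studies
#'
#' For each grouping, builds one subjects-by-sessions [CVTable-class] per
#' method: the default shim and the universal pulse applied to all grouping
#' sessions, and each tailored-pulse configuration belonging to the
#' grouping's sessions applied across all of them (so each TP table mixes
#' its tailored scan group with the others). Cluster statistics and pairwise
#' signed-rank tests (Bonferroni family = all method pairs within the
#' grouping) are recomputed.
#'
#' @param result A [StudyResult-class] (from [runStudy()], or with `cvGrid`
#'   and `groupings` populated).
#' @return The [StudyResult-class] with `tables`, `summaries` and `tests`
#'   filled in.
#' @export
groupStudies <- function(result) {
  cvGrid <- result@cvGrid
  sessionsPresent <- sort(unique(cvGrid$session))
  tables <- list()
  summaries <- list()
  tests <- list()
  for (g in names(result@groupings)) {
    sess <- result@groupings[[g]]
    bad <- setdiff(sess, sessionsPresent)
    if (length(bad))
      stop(sprintf("grouping '%s' references absent session(s) %s",
                   g, paste(bad, collapse = ", ")))
    tabs <- list()
    tabs$default <- .cvTableFor(cvGrid, "default", NA_integer_, sess)
    tabs$UP <- .cvTableFor(cvGrid, "UP", NA_integer_, sess)
    for (j in sess)
      tabs[[sprintf("TP.Config%d", j)]] <-
        .cvTableFor(cvGrid, "TP", j, sess)
    tables[[g]] <- tabs
    summaries[[g]] <- do.call(rbind, lapply(names(tabs), function(nm) {
      cs <- clusterSummary(tabs[[nm]])
      data.frame(grouping = g, method = nm, icv = cs@icv,
                 icvRoot = cs@icvRoot, centroidNorm = cs@centroidNorm,
                 perpDistance = cs@perpDistance,
                 medianCv = median(tabs[[nm]]@values),
                 stringsAsFactors = FALSE)
    }))
    tests[[g]] <- pairwiseRankTests(tabs)
  }
  result@tables <- tables
  result@summaries <- do.call(rbind, summaries)
  result@tests <- tests
  result
}

.cvTableFor <- function(cvGrid, method, config, sessions) {
  subjects <- sort(unique(cvGrid$subject))
  vals <- sapply(sessions, function(s) {
    sel <- cvGrid$method == method & cvGrid$session == s &
      (if (is.na(config)) is.na(cvGrid$config) else
        !is.na(cvGrid$config) & cvGrid$config == config)
    sub <- cvGrid[sel, ]
    sub <- sub[order(sub$subject), ]
    if (nrow(sub) != length(subjects))
      stop(sprintf("incomplete result grid for method %s, session %d",
                   method, s))
    sub$cv
  })
  vals <- matrix(vals, nrow = length(subjects))
  dimnames(vals) <- list(subject = subjects, session = sessions)
  nm <- if (is.na(config)) method else sprintf("TP.Config%d", config)
  cvTable(vals, method = nm)
}

#' Headline medians and orderings per grouping
#'
#' Median CV (percent) of the tailored pulses on their own scan groups
#' (TSG), on the other scan groups (nTSG), of the universal pulse and of the
#' default shim within each grouping, plus the corresponding median flip
#' angles and whether the universal pulse attains the smallest inertia and
#' perpendicular distance among all methods of the grouping.
#'
#' @param result A [StudyResult-class].
#' @return data.frame, one row per grouping.
#' @export
orderingSummary <- function(result) {
  cvGrid <- result@cvGrid
  out <- lapply(names(result@groupings), function(g) {
    sess <- result@groupings[[g]]
    inG <- cvGrid$session %in% sess
    tpG <- cvGrid$method == "TP" & inG & cvGrid$config %in% sess
    tsg <- tpG & cvGrid$config == cvGrid$session
    ntsg <- tpG & cvGrid$config != cvGrid$session
    upG <- cvGrid$method == "UP" & inG
    defG <- cvGrid$method == "default" & inG
    sm <- result@summaries[result@summaries$grouping == g, ]
    data.frame(
      grouping = g,
      medianCvTpTsg = median(cvGrid$cv[tsg]),
      medianCvUp = median(cvGrid$cv[upG]),
      medianCvTpNtsg = median(cvGrid$cv[ntsg]),
      medianCvDefault = median(cvGrid$cv[defG]),
      medianFaTpTsg = median(cvGrid$medianFa[tsg]),
      medianFaUp = median(cvGrid$medianFa[upG]),
      medianFaTpNtsg = median(cvGrid$medianFa[ntsg]),
      upMinIcv = sm$icv[sm$method == "UP"] == min(sm$icv),
      upMinDperp = sm$perpDistance[sm$method == "UP"] ==
        min(sm$perpDistance),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write the study tables and pulses to a directory
#'
#' Emits `cv_grid.csv`, per-grouping `cluster_summary_<g>.csv` and
#' `tests_<g>.csv`, every designed pulse as JSON under `pulses/`, and a
#' `run_manifest.json` with seeds and configuration echoes. Outputs are
#' byte-identical across runs with the same master seed.
#'
#' @param result A [StudyResult-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyTables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(result@cvGrid, file.path(dir, "cv_grid.csv"),
            row.names = FALSE)
  for (g in names(result@tables)) {
    sm <- result@summaries[result@summaries$grouping == g, ]
    write.csv(sm, file.path(dir, sprintf("cluster_summary_%s.csv", g)),
              row.names = FALSE)
    write.csv(result@tests[[g]], file.path(dir, sprintf("tests_%s.csv", g)),
              row.names = FALSE)
  }
  pd <- file.path(dir, "pulses")
  if (!dir.exists(pd)) dir.create(pd)
  writePulse(result@pulses$default, file.path(pd, "default.json"))
  writePulse(result@pulses$up, file.path(pd, "up.json"))
  for (v in seq_along(result@pulses$tp))
    for (s in seq_along(result@pulses$tp[[v]]))
      writePulse(result@pulses$tp[[v]][[s]],
                 file.path(pd, sprintf("tp_sub%02d_ses%02d.json", v, s)))
  manifest <- list(seed = result@seed, meta = result@meta[
    c("nSubjects", "nSessions", "librarySize")],
    groupings = result@groupings)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
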