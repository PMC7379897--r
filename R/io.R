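# Plain-text persistence of a cohort: one JSON manifest, one signals TSV and
# one R-peak-times file per subject-trial, one ratings CSV.

trial_stub <- function(tr) {
  sprintf("%s_%s_day%d_%s_t%02d", tr$dyad_id, tr$subject_id, tr$day,
          substr(tr$condition, 1, 5), tr$trial_index)
}

#' Write a cohort to a directory of plain-text files
#'
#' Layout: `manifest.json` (config echo, seed, file index), `ratings.csv`,
#' and per subject-trial `signals/<stub>.tsv` (columns `time_s`, `resp`,
#' `eda`, `ball_x`, `ball_y`, `target_x`, `target_y`) plus
#' `rpeaks/<stub>.txt` (one R-peak time in seconds per line).
#'
#' @param cohort a `dyadphys_cohort`.
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dyadphys_cohort"))
  dir.create(file.path(dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "rpeaks"), showWarnings = FALSE)
  stubs <- vapply(cohort$trials, trial_stub, character(1))
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    sig <- data.frame(time_s = tr$tracking$time_s, resp = tr$resp,
                      eda = tr$eda,
                      ball_x = tr$tracking$ball_x,
                      ball_y = tr$tracking$ball_y,
                      target_x = tr$tracking$target_x,
                      target_y = tr$tracking$target_y)
    utils::write.table(sig,
                       file.path(dir, "signals", paste0(stubs[i], ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(format(tr$rpeaks, digits = 10, trim = TRUE, scientific = FALSE),
               file.path(dir, "rpeaks", paste0(stubs[i], ".txt")))
  }
  utils::write.csv(cohort$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  meta <- lapply(seq_along(cohort$trials), function(i) {
    tr <- cohort$trials[[i]]
    list(stub = stubs[i], dyad = tr$dyad_id, subject = tr$subject_id,
         day = tr$day, condition = tr$condition, trial = tr$trial_index,
         own_axis = tr$own_axis)
  })
  jsonlite::write_json(
    list(config = unclass(cohort$config), trials = meta),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `dyadphys_cohort` (without the synthetic ground-truth
#'   attribute, which is not persisted).
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  cfg_args <- lapply(man$config, function(v) if (is.list(v)) unlist(v) else v)
  cfg <- do.call(cohort_config, cfg_args[names(cfg_args) != ""])
  ratings <- utils::read.csv(file.path(dir, "ratings.csv"))
  trials <- lapply(man$trials, function(m) {
    sig <- utils::read.table(
      file.path(dir, "signals", paste0(m$stub, ".tsv")),
      header = TRUE, sep = "\t")
    rp <- as.numeric(readLines(file.path(dir, "rpeaks",
                                         paste0(m$stub, ".txt"))))
    row <- ratings[ratings$subject == m$subject & ratings$day == m$day &
                     ratings$condition == m$condition &
                     ratings$trial == m$trial, ]
    collab <- m$condition == "collaborative"
    list(dyad_id = m$dyad, subject_id = m$subject, day = m$day,
         condition = m$condition, trial_index = m$trial,
         own_axis = m$own_axis, rpeaks = rp, resp = sig$resp,
         eda = sig$eda, fs = cfg$fs_resp_eda,
         tracking = sig[, c("time_s", "ball_x", "ball_y", "target_x",
                            "target_y")],
         ratings = list(R1 = row$R1[1],
                        R2 = if (collab) row$R2[1] else NULL,
                        R3 = if (collab) row$R3[1] else NULL))
  })
  structure(list(config = cfg, trials = trials, ratings = ratings),
            class = "dyadphys_cohort")
}
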