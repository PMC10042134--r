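#' Founder-cell Shannon entropy (fcSE)
#'
#' Diversity of the founder-clone composition of a GC:
#' `fcSE = -sum(p_i * log(p_i))` in natural-log units (nats), where `p_i` is
#' the mole fraction of clone i among all live B cells. A monoclonal (or, by
#' convention, empty) GC has fcSE 0; the maximum is `log(N)` for N clones.
#'
#' @param counts non-negative clone counts (zero counts are ignored).
#' @return non-negative entropy in nats.
#' @export
fcse <- function(counts) {
  if (any(counts < 0)) stop("clone counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Clonal dominance
#'
#' Mole fraction of the largest (dominant) B-cell clone. An empty census is
#' assigned dominance 1 by convention (consistent with fcSE 0 for a
#' collapsed GC).
#'
#' @param counts non-negative clone counts.
#' @return dominance in (0, 1].
#' @export
clonal_dominance <- function(counts) {
  if (any(counts < 0)) stop("clone counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(1)
  max(counts) / sum(counts)
}

#' Cumulative GC response (CGR)
#'
#' Product of the average GC B-cell affinity and the founder-cell Shannon
#' entropy; a single number combining affinity maturation and clonal
#' diversity.
#'
#' @param mean_affinity mean affinity in `[0, 1]`.
#' @param fcse entropy in nats.
#' @return non-negative CGR.
#' @export
cgr <- function(mean_affinity, fcse) {
  stopifnot(all(mean_affinity >= 0), all(mean_affinity <= 1), all(fcse >= 0))
  mean_affinity * fcse
}

#' Per-timepoint diversity metrics of a trajectory
#'
#' @param traj a [run_gc()] trajectory (or anything with a `census` tibble
#'   and a `summary` tibble carrying `time_h`, `size`, `mean_affinity`).
#' @return tibble with columns `time_h`, `size`, `n_clones`, `mean_affinity`,
#'   `fcse`, `dominance`, `cgr`, `collapsed`.
#' @export
trajectory_metrics <- function(traj) {
  div <- traj$census |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(fcse = fcse(.data$count),
                     dominance = clonal_dominance(.data$count),
                     .groups = "drop")
  out <- traj$summary |>
    dplyr::select("time_h", "size", "n_clones", "mean_affinity") |>
    dplyr::left_join(div, by = "time_h") |>
    dplyr::mutate(
      # empty-census convention: fcSE 0, dominance 1
      fcse = ifelse(is.na(.data$fcse), 0, .data$fcse),
      dominance = ifelse(is.na(.data$dominance), 1, .data$dominance),
      cgr = cgr(.data$mean_affinity, .data$fcse),
      collapsed = if (is.na(traj$collapse_h)) FALSE else
        .data$time_h >= traj$collapse_h
    )
  out
}

#' Aggregate replicate GC trajectories
#'
#' Per-timepoint mean and standard deviation of each metric across replicate
#' GCs. Following the inclusion rule used for population averages, collapsed
#' GCs contribute affinity 0, size 0, fcSE 0, CGR 0 and dominance 1 at all
#' times after their collapse (`rule = "include"`); `rule = "drop"` instead
#' removes collapsed GCs from the average after their collapse time.
#'
#' @param trajectories list of [run_gc()] trajectories on a common time grid.
#' @param rule collapsed-GC accounting rule.
#' @return tibble (`time_h`, `metric`, `mean`, `sd`, `n`, `n_collapsed`).
#' @export
aggregate_replicates <- function(trajectories, rule = c("include", "drop")) {
  rule <- match.arg(rule)
  stopifnot(length(trajectories) >= 1L)
  grids <- lapply(trajectories, function(x) x$summary$time_h)
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    stop("replicates are recorded on different time grids")
  }
  per <- lapply(seq_along(trajectories), function(i) {
    m <- trajectory_metrics(trajectories[[i]])
    if (any(m$collapsed)) {
      post <- m$collapsed
      m$size[post] <- 0L
      m$mean_affinity[post] <- 0
      m$fcse[post] <- 0
      m$cgr[post] <- 0
      m$dominance[post] <- 1
    }
    m$replicate <- i
    m
  })
  long <- dplyr::bind_rows(per) |>
    tidyr::pivot_longer(c("size", "n_clones", "mean_affinity", "fcse",
                          "dominance", "cgr"),
                        names_to = "metric", values_to = "value")
  if (rule == "drop") long <- dplyr::filter(long, !.data$collapsed)
  long |>
    dplyr::group_by(.data$time_h, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      n_collapsed = sum(.data$collapsed),
      .groups = "drop"
    )
}

#' Snapshot metrics at (nearest to) a given day
#'
#' Used for the day-18 violin-style summaries of fcSE and clonal dominance
#' across replicate GCs.
#'
#' @param trajectories list of trajectories.
#' @param day snapshot day; the recorded timepoint nearest `day * 24` h is
#'   used.
#' @param rule collapsed-GC accounting rule (see [aggregate_replicates()]).
#' @return tibble with one row per replicate (`replicate`, `time_h`, `size`,
#'   `mean_affinity`, `fcse`, `dominance`, `cgr`, `collapsed`).
#' @export
snapshot_metrics <- function(trajectories, day = 18,
                             rule = c("include", "drop")) {
  rule <- match.arg(rule)
  target <- day * 24
  rows <- lapply(seq_along(trajectories), function(i) {
    m <- trajectory_metrics(trajectories[[i]])
    j <- which.min(abs(m$time_h - target))
    r <- m[j, ]
    if (r$collapsed) {
      r$size <- 0L; r$mean_affinity <- 0; r$fcse <- 0; r$cgr <- 0
      r$dominance <- 1
    }
    r$replicate <- i
    r
  })
  out <- dplyr::bind_rows(rows)
  if (rule == "drop") out <- dplyr::filter(out, !.data$collapsed)
  dplyr::relocate(out, "replicate")
}
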