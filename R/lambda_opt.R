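## Lambda-window schedule construction: given a finely resolved predicted
## cumulative free-energy profile F(lambda), place the minimum number of
## windows so that the free-energy change between adjacent windows never
## exceeds a threshold (default 10 kcal/mol). See optimize_schedule for
## why reach-maximizing (not farthest-step) selection is the minimal
## strategy; the test suite checks minimality against an exhaustive
## dynamic program.

#' Predict a dense free-energy profile for scheduling
#'
#' Evaluates the model on the uniform grid `{0, res, 2*res, ..., 1}`
#' (default resolution 0.001, i.e. 1001 points).
#'
#' @param pair `alch_graph_pair`.
#' @param leg_id 1 or 2.
#' @param params `alch_params`.
#' @param resolution Grid spacing in lambda (default 0.001).
#' @return List with `lambda` (grid) and `F` (predicted cumulative free
#'   energies, kcal/mol; `F[1] = 0`).
#' @export
profile_grid <- function(pair, leg_id, params, resolution = 0.001) {
  stopifnot(resolution > 0, resolution < 1)
  grid <- seq(0, 1, by = resolution)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  prof <- predict_profile(pair, leg_id, grid, params)
  list(lambda = grid, F = prof$cumulative_dG)
}

# Max |F(k) - F(i)| over k in (i, j] ("interval" mode) or just at j
# ("endpoint" mode).
.jump_gap <- function(F, i, j, gap_mode) {
  if (gap_mode == "endpoint") abs(F[j] - F[i])
  else max(abs(F[(i + 1):j] - F[i]))
}

#' Optimize a lambda-window schedule
#'
#' Places the minimum number of windows on the grid such that every
#' adjacent gap stays within the threshold. In `"interval"` mode the set
#' of feasible jump targets from a window is a contiguous prefix (the
#' running-max gap is nondecreasing in the target), so the minimum-window
#' schedule is found by reach-maximizing jump selection: each next window
#' is the feasible point whose own feasible range extends farthest.
#' Naively jumping to the farthest feasible point is not minimal on
#' non-monotone profiles, because the gap is measured relative to the
#' window the jump starts from. In `"endpoint"` mode feasibility is not
#' contiguous and an explicit shortest-path recursion over the grid is
#' used. Ties are broken toward larger lambda (fewest windows on flat
#' plateaus). The test suite checks minimality against an exhaustive
#' dynamic program over all grid subsets.
#'
#' @param grid Sorted lambda grid covering the leg (first value 0).
#' @param F Cumulative free energies on the grid (kcal/mol, `F[1] = 0`).
#' @param threshold Maximum allowed adjacent free-energy gap in kcal/mol
#'   (default 10).
#' @param gap_mode `"interval"` (default): the gap of a jump is the maximum
#'   deviation of F over the whole jump interval from its start — a
#'   conservative reading that also guards non-monotone profiles;
#'   `"endpoint"`: only the endpoint difference counts.
#' @param tol Numerical tolerance on the threshold comparison (default
#'   1e-9 kcal/mol), so that gaps equal to the threshold up to
#'   floating-point rounding count as feasible.
#' @return Object of class `alch_schedule`: `lam_values`, `threshold`,
#'   `max_adjacent_gap`, `n_windows`, `gap_mode`.
#' @export
optimize_schedule <- function(grid, F, threshold = 10,
                              gap_mode = c("interval", "endpoint"),
                              tol = 1e-9) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(threshold > 0, length(grid) == length(F), length(grid) >= 2)
  if (is.unsorted(grid, strictly = TRUE))
    alch_stop("grid must be strictly increasing", "alch_domain_error")
  if (!all(is.finite(F)))
    alch_stop("non-finite free energies in profile", "alch_domain_error")
  n <- length(grid)
  sched <- if (gap_mode == "interval")
    .schedule_interval(grid, F, threshold, tol) else
      .schedule_endpoint(grid, F, threshold, tol)
  gaps <- vapply(seq_len(length(sched) - 1), function(k)
    .jump_gap(F, sched[k], sched[k + 1], gap_mode), numeric(1))
  structure(list(lam_values = grid[sched], threshold = threshold,
                 max_adjacent_gap = max(gaps),
                 n_windows = length(sched), gap_mode = gap_mode),
            class = "alch_schedule")
}

# Interval mode: reach[i] = farthest j with running-max gap <= threshold;
# minimal schedule by always stepping to the candidate with maximal reach.
.schedule_interval <- function(grid, F, threshold, tol) {
  n <- length(grid)
  reach <- integer(n)
  reach[n] <- n
  for (i in seq_len(n - 1)) {
    rmax <- cummax(abs(F[(i + 1):n] - F[i]))
    bad <- which(rmax > threshold + tol)
    reach[i] <- if (length(bad) == 0) n else i + bad[1] - 1L
  }
  sched <- 1L
  cur <- 1L
  while (cur < n) {
    if (reach[cur] <= cur)
      alch_stop(sprintf(
        "infeasible: grid step [%g, %g] already exceeds %g kcal/mol (gap %.3f)",
        grid[cur], grid[cur + 1L], threshold,
        abs(F[cur + 1L] - F[cur])), "alch_infeasible_error")
    if (reach[cur] >= n) {
      sched <- c(sched, n)
      break
    }
    cand <- (cur + 1L):reach[cur]
    best <- max(reach[cand])
    nxt <- max(cand[reach[cand] == best])  # tie-break: largest lambda
    sched <- c(sched, nxt)
    cur <- nxt
  }
  sched
}

# Endpoint mode: minimum-window shortest path; predecessors chosen as late
# as possible on ties.
.schedule_endpoint <- function(grid, F, threshold, tol) {
  n <- length(grid)
  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  dist[1] <- 1
  for (j in 2:n) {
    i <- seq_len(j - 1)
    feas <- i[abs(F[i] - F[j]) <= threshold + tol & is.finite(dist[i])]
    if (length(feas) > 0) {
      dmin <- min(dist[feas])
      prev[j] <- max(feas[dist[feas] == dmin])
      dist[j] <- dmin + 1
    }
  }
  if (!is.finite(dist[n])) {
    step <- which(abs(diff(F)) > threshold + tol)
    msg <- if (length(step) > 0)
      sprintf("infeasible: grid step [%g, %g] exceeds %g kcal/mol",
              grid[step[1]], grid[step[1] + 1], threshold)
    else sprintf("infeasible: no window sequence reaches lambda = %g under %g kcal/mol",
                 grid[n], threshold)
    alch_stop(msg, "alch_infeasible_error")
  }
  sched <- n
  while (!is.na(prev[sched[1]])) sched <- c(prev[sched[1]], sched)
  sched
}

#' @export
print.alch_schedule <- function(x, ...) {
  cat(sprintf(
    "<alch_schedule: %d windows, max adjacent gap %.3f kcal/mol (threshold %g)>\n",
    x$n_windows, x$max_adjacent_gap, x$threshold))
  invisible(x)
}

#' Verify a lambda schedule against a profile
#'
#' Recomputes every adjacent gap on the grid; feasible if and only if the
#' maximum gap is within the threshold.
#'
#' @param schedule `alch_schedule`, or a plain numeric vector of lambda
#'   values present on the grid.
#' @param grid Lambda grid.
#' @param F Cumulative free energies on the grid.
#' @param threshold Gap threshold (default: the schedule's own, or 10).
#' @param gap_mode `"interval"` or `"endpoint"` (default: the schedule's
#'   own, or `"interval"`).
#' @param tol Numerical tolerance on the threshold comparison (default
#'   1e-9 kcal/mol).
#' @return List `feasible`, `max_gap` (kcal/mol), `n_windows`.
#' @export
verify_schedule <- function(schedule, grid, F, threshold = NULL,
                            gap_mode = NULL, tol = 1e-9) {
  if (inherits(schedule, "alch_schedule")) {
    lam <- schedule$lam_values
    if (is.null(threshold)) threshold <- schedule$threshold
    if (is.null(gap_mode)) gap_mode <- schedule$gap_mode
  } else lam <- as.numeric(schedule)
  if (is.null(threshold)) threshold <- 10
  if (is.null(gap_mode)) gap_mode <- "interval"
  pos <- match(round(lam, 12), round(grid, 12))
  if (any(is.na(pos)))
    alch_stop("schedule contains lambda values not on the grid",
              "alch_domain_error")
  gaps <- vapply(seq_len(length(pos) - 1), function(k)
    .jump_gap(F, pos[k], pos[k + 1], gap_mode), numeric(1))
  max_gap <- if (length(gaps) > 0) max(gaps) else 0
  list(feasible = max_gap <= threshold + tol, max_gap = max_gap,
       n_windows = length(pos))
}

#' Write a schedule as JSON and a plain lambda list
#'
#' @param schedule `alch_schedule`.
#' @param json_path Output JSON path.
#' @param txt_path Optional plain-text path (one lambda per line) in the
#'   form consumed by AToM-OpenMM-style configuration files.
#' @return `json_path`, invisibly.
#' @export
write_schedule <- function(schedule, json_path, txt_path = NULL) {
  jsonlite::write_json(unclass(schedule), json_path, digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(txt_path))
    writeLines(format(schedule$lam_values, trim = TRUE), txt_path)
  invisible(json_path)
}
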