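# Segregation-index metrics: contact census C_ij and psi, bulk and per radial
# region.

#' Contact pairs of a snapshot
#'
#' All unordered particle pairs whose centre distance is at most
#' `(r_i + r_j) * (1 + tolerance)`. This geometric-proximity definition is
#' deliberately decoupled from the force-model overlap so that it is robust to
#' snapshot rounding; `tolerance = 0` counts only overlapping pairs.
#'
#' @param snapshot a `trajectory_snapshot`
#' @param tolerance relative distance slack (dimensionless, >= 0)
#' @return integer matrix with columns `i`, `j` (row indices into the snapshot)
#' @export
contact_pairs <- function(snapshot, tolerance = 1e-3) {
  stopifnot(tolerance >= 0)
  p <- snapshot$particles
  if (is.null(p) || nrow(p) == 0)
    stop("empty snapshot: no particles to census", call. = FALSE)
  .contact_pairs_cpp(cbind(p$x, p$y, p$z), p$radius, tolerance)
}

census_from_pairs <- function(labels, pairs, region_id = NA) {
  li <- labels[pairs[, 1]]
  lj <- labels[pairs[, 2]]
  # ordered-contact convention: each unordered pair is credited to both
  # orderings, so a like-label contact counts twice in C11 (or C22) and a
  # cross contact once in each of C12 and C21 (making C12 = C21 identical).
  # This is the convention under which uniform random mixing gives psi = 1.
  c11 <- 2L * sum(li == 1L & lj == 1L)
  c22 <- 2L * sum(li == 2L & lj == 2L)
  c12 <- sum(li != lj)
  structure(list(C11 = c11, C12 = c12, C21 = c12, C22 = c22,
                 region_id = region_id),
            class = "contact_census")
}

#' Contact census between particle labels
#'
#' Counts the contacts between particles of type 1 and 2 under the
#' ordered-contact convention: each unordered pair is credited to both
#' orderings, so a 1-1 contact adds 2 to `C11`, and a 1-2 contact adds 1 to
#' each of `C12` and `C21` (hence `C12 = C21` identically). Under this
#' convention random 50/50 labels give a segregation index of 1 in
#' expectation.
#'
#' @inheritParams contact_pairs
#' @return a `contact_census` with fields `C11`, `C12`, `C21`, `C22`
#' @export
contact_census <- function(snapshot, tolerance = 1e-3) {
  pairs <- contact_pairs(snapshot, tolerance)
  census_from_pairs(snapshot$particles$label, pairs)
}

#' @exportS3Method base::print
print.contact_census <- function(x, ...) {
  cat(sprintf("Contact census: C11 = %d, C12 = C21 = %d, C22 = %d\n",
              x$C11, x$C12, x$C22))
  invisible(x)
}

#' Segregation index psi of a contact census
#'
#' `psi = C11 / (C11 + C12) + C22 / (C22 + C21)`. psi = 1 corresponds to
#' uniform random mixing, psi = 2 to a completely unmixed bed, and psi = 0 to a
#' perfectly alternating arrangement with only cross-type contacts.
#'
#' @param census a `contact_census`
#' @return psi in \[0, 2\]; an error if either label has no contacts at all
#'   (psi is then undefined, which is distinct from psi = 0)
#' @export
segregation_index <- function(census) {
  stopifnot(inherits(census, "contact_census"))
  d1 <- census$C11 + census$C12
  d2 <- census$C22 + census$C21
  if (d1 == 0 || d2 == 0)
    stop(sprintf(paste0("segregation index undefined: label %s has no contacts ",
                        "(C11=%d C12=%d C21=%d C22=%d)"),
                 if (d1 == 0) "1" else "2", census$C11, census$C12,
                 census$C21, census$C22), call. = FALSE)
  census$C11 / d1 + census$C22 / d2
}

#' Per-region contact census over radial annuli
#'
#' Partitions the bed into `n_regions` equal-width annuli in cylindrical radius
#' from the vessel axis to the wall (R1 closest to the axis). Each contact is
#' assigned to the annulus containing the contact midpoint.
#'
#' @inheritParams contact_pairs
#' @param n_regions number of radial regions
#' @param geometry a [vessel_geometry()]; its radius sets the outer edge
#' @return list of `contact_census`, one per region, with attribute
#'   `region_edges` (annulus boundaries in m)
#' @export
radial_partition <- function(snapshot, n_regions = 3, geometry,
                             tolerance = 1e-3) {
  stopifnot(n_regions >= 1)
  pairs <- contact_pairs(snapshot, tolerance)
  p <- snapshot$particles
  edges <- seq(0, geometry$vessel_radius, length.out = n_regions + 1)
  mx <- (p$x[pairs[, 1]] + p$x[pairs[, 2]]) / 2
  my <- (p$y[pairs[, 1]] + p$y[pairs[, 2]]) / 2
  rad <- sqrt(mx^2 + my^2)
  reg <- pmin(pmax(findInterval(rad, edges, rightmost.closed = TRUE), 1L),
              n_regions)
  out <- lapply(seq_len(n_regions), function(k) {
    census_from_pairs(p$label, pairs[reg == k, , drop = FALSE],
                      region_id = paste0("R", k))
  })
  attr(out, "region_edges") <- edges
  out
}

#' Segregation-index time series from a trajectory
#'
#' Computes the bulk segregation index and (optionally) per-radial-region
#' indices for every snapshot. A region where psi is undefined (a label with no
#' contacts there) is reported as `NA`, never interpolated.
#'
#' @param traj a `granumix_trajectory` or list of snapshots
#' @param n_regions radial regions (1 = bulk only)
#' @param tolerance contact-distance slack, see [contact_pairs()]
#' @param geometry a [vessel_geometry()]; taken from the trajectory attributes
#'   when NULL
#' @param rpm impeller speed for the revolutions column; taken from the
#'   trajectory when NULL
#' @return a `segregation_series` data.frame with columns `time`,
#'   `revolutions`, `psi_bulk` and `psi_R1` ... `psi_Rn`
#' @export
series_from_trajectory <- function(traj, n_regions = 3, tolerance = 1e-3,
                                   geometry = NULL, rpm = NULL) {
  if (length(traj) < 2)
    stop("need at least 2 snapshots for a series", call. = FALSE)
  if (is.null(geometry)) geometry <- attr(traj, "geometry")
  if (is.null(rpm)) {
    pp <- attr(traj, "params")
    rpm <- if (!is.null(pp)) pp$rpm else traj[[2]]$revolutions * 60 / traj[[2]]$time
  }
  times <- vapply(traj, function(s) s$time, 0)
  if (any(diff(times) <= 0))
    stop("snapshot times must be strictly increasing", call. = FALSE)
  psi_of <- function(census, t) {
    tryCatch(segregation_index(census), error = function(e) NA_real_)
  }
  rows <- lapply(traj, function(s) {
    bulk <- psi_of(contact_census(s, tolerance), s$time)
    row <- data.frame(time = s$time, revolutions = rpm * s$time / 60,
                      psi_bulk = bulk)
    if (n_regions > 1) {
      if (is.null(geometry))
        stop("per-region psi needs a vessel geometry", call. = FALSE)
      cs <- radial_partition(s, n_regions, geometry, tolerance)
      for (k in seq_len(n_regions))
        row[[paste0("psi_R", k)]] <- psi_of(cs[[k]], s$time)
    }
    row
  })
  out <- do.call(rbind, rows)
  if (n_regions > 1)
    attr(out, "region_edges") <- seq(0, geometry$vessel_radius,
                                     length.out = n_regions + 1)
  class(out) <- c("segregation_series", "data.frame")
  out
}

#' Write / read a segregation-index series CSV
#'
#' Columns: `time`, `revolutions`, `psi_bulk` and any `psi_R*` region columns.
#' `read_segregation_series` also accepts a bare two-column `(t, psi)` CSV.
#'
#' @param series a `segregation_series` data.frame
#' @param file CSV path
#' @return the file path (write) or a `segregation_series` (read)
#' @export
write_segregation_series <- function(series, file) {
  write.csv(as.data.frame(series), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_segregation_series
#' @export
read_segregation_series <- function(file) {
  d <- read.csv(file)
  if (!"psi_bulk" %in% names(d)) {
    if (ncol(d) < 2)
      stop("series CSV needs at least (t, psi) columns", call. = FALSE)
    names(d)[1:2] <- c("time", "psi_bulk")
  }
  if (!"revolutions" %in% names(d)) d$revolutions <- NA_real_
  d <- d[c("time", "revolutions", "psi_bulk",
           setdiff(names(d), c("time", "revolutions", "psi_bulk")))]
  class(d) <- c("segregation_series", "data.frame")
  d
}
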