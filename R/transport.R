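ELEMENTARY_CHARGE <- 1.602176634e-19   # C

#' Define the filter binding sites from coordinating oxygens
#'
#' Each site S1-S5 is the volume between two four-oxygen planes (upper and
#' lower coordinating carbonyl/hydroxyl oxygens), realized as the z-slab
#' between the plane mean z-levels intersected with a cylinder of
#' \code{radial_cutoff} around the pore axis. S0 sits above the top plane,
#' bounded above by a fixed offset.
#'
#' @param planes list of 6 integer vectors of oxygen atom ids, ordered
#'   from the lowest (intracellular) plane to the highest
#' @param radial_cutoff lateral extent of each site (Angstrom, default 3)
#' @param s0_offset upper bound of S0 above the top plane (default 3.1)
#' @return object of class \code{binding_site_set}
#' @export
binding_site_set <- function(planes, radial_cutoff = 3, s0_offset = 3.1) {
  if (length(planes) != 6) stop("binding_site_set: need 6 oxygen planes")
  sites <- lapply(1:5, function(i)
    list(label = paste0("S", 6 - i), lower = planes[[i]],
         upper = planes[[i + 1]]))
  sites[[6]] <- list(label = "S0", lower = planes[[6]], upper = NULL)
  for (s in sites)
    if (anyDuplicated(c(s$lower, s$upper)))
      stop("binding_site_set: the coordinating oxygens of ", s$label,
           " are not distinct")
  structure(list(sites = sites, radial_cutoff = radial_cutoff,
                 s0_offset = s0_offset), class = "binding_site_set")
}

#' Build binding sites from a synthetic scaffold
#' @param scaffold output of \code{\link{make_filter_scaffold}}
#' @param radial_cutoff lateral site extent (Angstrom)
#' @return a \code{binding_site_set}
#' @export
scaffold_binding_sites <- function(scaffold, radial_cutoff = 3) {
  planes <- cage_oxygen_ids(scaffold)
  planes <- planes[order(as.numeric(names(planes)))]
  binding_site_set(unname(planes), radial_cutoff = radial_cutoff,
                   s0_offset = scaffold$spec$s0_offset)
}

#' Read / write binding-site definitions as JSON
#' @param path JSON path ({"S4": {"upper": [ids], "lower": [ids]}, ...})
#' @param radial_cutoff,s0_offset see \code{\link{binding_site_set}}
#' @return a \code{binding_site_set}
#' @export
read_binding_sites <- function(path, radial_cutoff = 3, s0_offset = 3.1) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  labs <- paste0("S", 5:0)
  if (!all(labs %in% names(j)))
    stop("read_binding_sites: need entries S0..S5")
  planes <- c(list(j[["S5"]]$lower),
              lapply(5:1, function(k) j[[paste0("S", k)]]$upper))
  binding_site_set(lapply(planes, as.integer), radial_cutoff, s0_offset)
}

#' @rdname read_binding_sites
#' @param sites a \code{binding_site_set}
#' @export
write_binding_sites <- function(sites, path) {
  out <- lapply(sites$sites, function(s)
    list(lower = s$lower, upper = s$upper))
  names(out) <- vapply(sites$sites, `[[`, "", "label")
  jsonlite::write_json(out, path, auto_unbox = FALSE)
  invisible(path)
}

# per-frame z-slab bounds of each site, from oxygen positions
site_bounds_frame <- function(sites, xyz) {
  t(vapply(sites$sites, function(s) {
    lo <- mean(xyz[s$lower + 1L, 3])
    hi <- if (is.null(s$upper)) lo + sites$s0_offset
          else mean(xyz[s$upper + 1L, 3])
    c(lo, hi)
  }, numeric(2)))
}

#' Assign tracked particles to binding sites, cavity, extracellular, bulk
#'
#' A particle is in site i when its z lies between the mean z-levels of
#' the site's lower and upper oxygen planes (ties at a shared boundary go
#' to the lower site) and its radial distance to the pore axis is at most
#' the site's radial cutoff. Below the filter and within
#' \code{cavity_radius} of the axis it is in the cavity; above the S0
#' upper bound it is extracellular; anything else is bulk.
#'
#' @param oriented \code{oriented_frames} (pore axis = +z)
#' @param topo matching topology
#' @param sites a \code{binding_site_set}
#' @param tracked atom ids of ions or water oxygens to follow
#' @param cavity_radius lateral extent of the cavity (Angstrom, default 5)
#' @return object of class \code{site_assignment}: character matrix
#'   [frames x particles] plus metadata
#' @export
assign_sites <- function(oriented, topo, sites, tracked,
                         cavity_radius = 5) {
  traj <- oriented$trajectory
  check_traj_topo(traj, topo)
  rows <- tracked + 1L
  labels <- vapply(sites$sites, `[[`, "", "label")
  nf <- traj$n_frames
  out <- matrix("", nf, length(tracked),
                dimnames = list(NULL, as.character(tracked)))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    b <- site_bounds_frame(sites, xyz)
    ord <- order(b[, 1])
    if (any(b[ord, 1][-1] < b[ord, 2][-length(ord)] - 1e-9))
      stop("assign_sites: overlapping site slabs (geometry error)")
    zmin <- min(b[, 1]); zmax <- max(b[, 2])
    for (k in seq_along(rows)) {
      p <- xyz[rows[k], ]
      r <- sqrt(p[1]^2 + p[2]^2)
      lab <- "bulk"
      # intervals are (lo, hi]: z exactly on a shared plane belongs to
      # the lower site (deterministic tie-break)
      hit <- which(p[3] > b[, 1] & p[3] <= b[, 2])
      if (length(hit) && r <= sites$radial_cutoff) {
        lab <- labels[hit[which.min(b[hit, 1])]]
      } else if (p[3] <= zmin && r <= cavity_radius) {
        lab <- "cavity"
      } else if (p[3] > zmax) {
        lab <- "extracellular"
      }
      out[f, k] <- lab
    }
  }
  structure(list(labels = out, tracked = tracked, n_frames = nf,
                 site_labels = labels), class = "site_assignment")
}

#' Binding-site occupancy f_i
#'
#' The mean number of tracked particles found in the site per frame:
#' the sum over frames and particles of the in-site indicator divided by
#' the number of frames. Equals 1 when exactly one particle sits in the
#' site in every frame, and can exceed 1 when several particles co-occupy
#' the site.
#'
#' @param series a \code{site_assignment}
#' @param site site label (e.g. "S2")
#' @return occupancy fraction (>= 0)
#' @export
occupancy <- function(series, site) {
  if (!site %in% c(series$site_labels, "cavity", "extracellular", "bulk"))
    stop("occupancy: unknown site label '", site, "'")
  sum(series$labels == site) / series$n_frames
}

#' Per-frame configuration strings of the filter
#'
#' The filter state at each frame rendered in the field's curly-brace
#' notation over S1..S5: the site label when an ion is present (ion
#' presence wins), "W" when only water, "0" when vacant — e.g.
#' "\{W,S2,W,S4,S5\}".
#'
#' @param ion_series \code{site_assignment} of the ions
#' @param water_series \code{site_assignment} of the water oxygens
#'   (optional; omit for an ion-only rendering)
#' @return character vector, one string per frame
#' @export
configuration_series <- function(ion_series, water_series = NULL) {
  nf <- ion_series$n_frames
  if (!is.null(water_series) && water_series$n_frames != nf)
    stop("configuration_series: frame counts differ")
  labs <- paste0("S", 1:5)
  vapply(seq_len(nf), function(f) {
    sym <- vapply(labs, function(s) {
      if (any(ion_series$labels[f, ] == s)) s
      else if (!is.null(water_series) &&
               any(water_series$labels[f, ] == s)) "W"
      else "0"
    }, character(1))
    paste0("{", paste(sym, collapse = ","), "}")
  }, character(1))
}

#' Count full permeation events
#'
#' An outward event is a particle passing cavity -> filter sites ->
#' extracellular without returning to the cavity in between (mirror rule
#' for inward). A bulk excursion (leaving the pore laterally) cancels a
#' pending traversal. Events are disjoint in time per particle.
#'
#' @param series a \code{site_assignment}
#' @return data.frame with \code{particle_id}, \code{entry_frame} (first
#'   frame inside the filter), \code{exit_frame} (first frame in the
#'   destination compartment) and \code{direction}
#' @export
count_permeations <- function(series) {
  filter_labs <- series$site_labels
  ev <- list()
  for (k in seq_along(series$tracked)) {
    anchor <- "none"; passed <- FALSE; entry <- NA_integer_
    for (f in seq_len(series$n_frames)) {
      L <- series$labels[f, k]
      if (L == "cavity") {
        if (anchor == "extracellular" && passed)
          ev[[length(ev) + 1]] <- data.frame(
            particle_id = series$tracked[k], entry_frame = entry,
            exit_frame = f, direction = "inward")
        anchor <- "cavity"; passed <- FALSE; entry <- NA_integer_
      } else if (L == "extracellular") {
        if (anchor == "cavity" && passed)
          ev[[length(ev) + 1]] <- data.frame(
            particle_id = series$tracked[k], entry_frame = entry,
            exit_frame = f, direction = "outward")
        anchor <- "extracellular"; passed <- FALSE; entry <- NA_integer_
      } else if (L %in% filter_labs) {
        if (anchor != "none" && !passed) { passed <- TRUE; entry <- f }
      } else {  # bulk
        anchor <- "none"; passed <- FALSE; entry <- NA_integer_
      }
    }
  }
  if (!length(ev))
    return(data.frame(particle_id = integer(), entry_frame = integer(),
                      exit_frame = integer(), direction = character()))
  do.call(rbind, ev)
}

#' Single-channel current inferred from permeation counts
#'
#' I = n q / t with q in elementary charges and t in ns, reported in pA.
#'
#' @param n_events number of full permeation events
#' @param duration_ns trajectory duration in ns
#' @param charge_per_event charge per event in elementary charges
#' @return current in pA
#' @export
inferred_current <- function(n_events, duration_ns, charge_per_event = 1) {
  if (duration_ns <= 0) stop("inferred_current: duration must be > 0")
  n_events * charge_per_event * ELEMENTARY_CHARGE /
    (duration_ns * 1e-9) * 1e12
}

#' Write a site-assignment series (or events) as CSV
#' @param series a \code{site_assignment}
#' @param path output CSV path
#' @export
write_site_assignment <- function(series, path) {
  df <- data.frame(frame = seq_len(series$n_frames), series$labels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
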