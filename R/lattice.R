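#' Micropattern lattice geometry
#'
#' A square array of circular activating features (alpha-CD3 + alpha-CD28
#' spots) with ICAM-1 in between. Features of diameter 2 um sit at a
#' centre-to-centre pitch of 15 um; a cell "encounters" a feature when its
#' contact zone can overlap it, so the encounter radius is the feature
#' radius plus a cell contact radius. Encounter discs of distinct features
#' must not overlap (encounter radius < pitch / 2).
#'
#' @param feature_diameter feature diameter in um (default 2).
#' @param pitch centre-to-centre spacing in um (default 15).
#' @param cell_contact_radius radius of the cell's contact footprint in um
#'   (default 4, a typical T-cell footprint).
#' @return an object of class `lattice` with the derived `encounter_radius`.
#' @export
lattice <- function(feature_diameter = 2, pitch = 15, cell_contact_radius = 4) {
  if (feature_diameter <= 0 || feature_diameter >= pitch)
    stop("need 0 < feature_diameter < pitch")
  r_enc <- feature_diameter / 2 + cell_contact_radius
  if (r_enc >= pitch / 2)
    stop("encounter discs overlap: encounter_radius must be < pitch/2")
  structure(list(feature_diameter = feature_diameter, pitch = pitch,
                 cell_contact_radius = cell_contact_radius,
                 encounter_radius = r_enc),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("Square feature lattice: %.3g um features at %.3g um pitch (encounter radius %.3g um)\n",
              x$feature_diameter, x$pitch, x$encounter_radius))
  invisible(x)
}

# id string for the feature at lattice indices (i, j)
feature_id <- function(i, j) paste(i, j, sep = ",")

feature_center <- function(lat, id) {
  ij <- as.numeric(strsplit(id, ",", fixed = TRUE)[[1]])
  ij * lat$pitch
}

# feature whose encounter disc contains (x, y), or NA (discs are disjoint,
# so only the nearest centre needs checking)
feature_at <- function(lat, x, y) {
  i <- round(x / lat$pitch); j <- round(y / lat$pitch)
  d2 <- (x - i * lat$pitch)^2 + (y - j * lat$pitch)^2
  ifelse(d2 <= lat$encounter_radius^2, feature_id(i, j), NA_character_)
}

# Intersections of the segment p0 -> p1 with every encounter disc.
# Returns a data.frame (feature, s_in, s_out) with s in [0, 1] along the
# segment, ordered by s_in. Disjoint discs mean the intervals are disjoint.
segment_disc_hits <- function(lat, p0, p1) {
  d <- p1 - p0
  R2 <- lat$encounter_radius^2
  pad <- lat$encounter_radius
  ir <- round((range(p0[1], p1[1]) + c(-pad, pad)) / lat$pitch)
  jr <- round((range(p0[2], p1[2]) + c(-pad, pad)) / lat$pitch)
  a <- sum(d * d)
  feat <- character(0); s_in <- numeric(0); s_out <- numeric(0)
  for (i in ir[1]:ir[2]) for (j in jr[1]:jr[2]) {
    fx <- p0[1] - i * lat$pitch; fy <- p0[2] - j * lat$pitch
    ff <- fx * fx + fy * fy
    if (a == 0) {                       # degenerate: stationary segment
      if (ff <= R2) {
        feat <- c(feat, feature_id(i, j)); s_in <- c(s_in, 0); s_out <- c(s_out, 1)
      }
      next
    }
    b <- 2 * (fx * d[1] + fy * d[2])
    disc <- b * b - 4 * a * (ff - R2)
    if (disc <= 0) next                 # miss (tangency ignored)
    sq <- sqrt(disc)
    s1 <- (-b - sq) / (2 * a); s2 <- (-b + sq) / (2 * a)
    if (s2 < 0 || s1 > 1) next
    feat <- c(feat, feature_id(i, j))
    s_in <- c(s_in, max(s1, 0)); s_out <- c(s_out, min(s2, 1))
  }
  res <- data.frame(feature = feat, s_in = s_in, s_out = s_out,
                    stringsAsFactors = FALSE)
  res[order(res$s_in), , drop = FALSE]
}

# Encounter events of a polyline path: maximal intervals during which the
# (linearly interpolated) centroid lies inside one feature's encounter disc.
# Starting inside a disc counts as an encounter at t[1]. Re-entry into the
# same feature is a new event.
# t in seconds; xy an n x 2 matrix. Returns data.frame(feature, t_in, t_out).
path_encounters <- function(lat, t, xy) {
  eps <- 1e-9
  events <- list()
  cur <- feature_at(lat, xy[1, 1], xy[1, 2])
  if (!is.na(cur))
    events[[1L]] <- list(feature = cur, t_in = t[1], t_out = NA_real_)
  n <- nrow(xy)
  if (n >= 2) for (k in 1:(n - 1)) {
    hits <- segment_disc_hits(lat, xy[k, ], xy[k + 1, ])
    dt <- t[k + 1] - t[k]
    inside_end <- NA_character_
    for (h in seq_len(nrow(hits))) {
      fid <- hits$feature[h]; s_in <- hits$s_in[h]; s_out <- hits$s_out[h]
      if (s_in <= eps && !is.na(cur) && cur == fid) {
        # continuation of the current encounter
        if (s_out < 1 - eps) {
          events[[length(events)]]$t_out <- t[k] + s_out * dt
          cur <- NA_character_
        } else inside_end <- fid
      } else {
        events[[length(events) + 1L]] <-
          list(feature = fid, t_in = t[k] + s_in * dt, t_out = NA_real_)
        if (s_out < 1 - eps) {
          events[[length(events)]]$t_out <- t[k] + s_out * dt
        } else inside_end <- fid
      }
    }
    if (!is.na(cur) && (is.na(inside_end) || inside_end != cur) &&
        nrow(hits) == 0) {
      # numerically grazed out between frames
      events[[length(events)]]$t_out <- t[k]
      cur <- NA_character_
    }
    cur <- inside_end
  }
  if (length(events) && is.na(events[[length(events)]]$t_out))
    events[[length(events)]]$t_out <- t[n]
  if (!length(events))
    return(data.frame(feature = character(), t_in = numeric(),
                      t_out = numeric(), stringsAsFactors = FALSE))
  data.frame(feature = vapply(events, `[[`, "", "feature"),
             t_in = vapply(events, `[[`, 0, "t_in"),
             t_out = vapply(events, `[[`, 0, "t_out"),
             stringsAsFactors = FALSE)
}
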