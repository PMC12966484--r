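#' Build an electrode table
#'
#' @param name character vector of bipolar electrode (virtual channel) names.
#' @param region brain-region label per electrode.
#' @param hemisphere `"L"` or `"R"` per electrode (recycled).
#' @param xyz numeric matrix (n x 3) of coordinates in mm; if `NULL`,
#'   electrodes are placed deterministically on a coarse grid so that
#'   pairwise distances are non-degenerate.
#'
#' @return data.frame with columns `name, region, hemisphere, x, y, z`.
#' @export
make_electrodes <- function(name, region, hemisphere = "L", xyz = NULL) {
  n <- length(name)
  stopifnot(n >= 1, length(region) == n)
  hemisphere <- rep_len(hemisphere, n)
  if (is.null(xyz)) {
    # deterministic non-collinear layout, ~15-40 mm apart
    i <- seq_len(n) - 1
    xyz <- cbind(20 * (i %% 3), 25 * (i %/% 3), 7 * ((i * 3) %% 5))
  }
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == n, ncol(xyz) == 3)
  data.frame(name = as.character(name), region = as.character(region),
             hemisphere = hemisphere,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Pairwise inter-electrode distances
#'
#' Euclidean distances between electrode coordinates (mm). Symmetric with a
#' zero diagonal; as a metric it satisfies the triangle inequality.
#'
#' @param electrodes electrode table from [make_electrodes()].
#' @return symmetric numeric matrix with electrode names as dimnames.
#' @export
electrode_distances <- function(electrodes) {
  m <- as.matrix(dist(electrodes[, c("x", "y", "z")]))
  dimnames(m) <- list(electrodes$name, electrodes$name)
  m
}

#' Ground-truth directed network for simulation
#'
#' Defines, for each directed electrode pair, the true probability that a
#' single pulse evokes a response, the response latency and amplitude, a
#' sigmoidal dependence on stimulation intensity, and per-state gains that
#' modulate both probability and amplitude in NREM/REM sleep relative to
#' wake. `true_probability` and `amplitude` are referenced to the 3 mA
#' mapping intensity: the intensity sigmoid is applied relative to its value
#' at 3 mA, so mapping blocks realise the stated probability directly.
#'
#' @param electrodes electrode table ([make_electrodes()]).
#' @param connections data.frame with columns `from`, `to` and optionally
#'   `prob`, `latency_ms`, `amplitude`, `sigmoid_mid_ma`, `sigmoid_slope_ma`,
#'   `gain_w`, `gain_nrem`, `gain_rem`; missing columns are filled with the
#'   defaults below. `NULL` means no connections (a null network).
#' @param prob,latency_ms,amplitude,sigmoid_mid_ma,sigmoid_slope_ma,gain_w,gain_nrem,gain_rem
#'   defaults used to fill missing columns. Amplitude is in the same units
#'   as the background noise standard deviation (`noise_sd` of
#'   [simulate_session()]), so `amplitude = 50` with `noise_sd = 10` is a
#'   5x-noise response.
#'
#' @return list of class `gt_network` with elements `electrodes`,
#'   `connections`, `distances`.
#' @export
make_network <- function(electrodes, connections = NULL,
                         prob = 0.8, latency_ms = 40, amplitude = 50,
                         sigmoid_mid_ma = 2, sigmoid_slope_ma = 1,
                         gain_w = 1, gain_nrem = 1, gain_rem = 1) {
  stopifnot(is.data.frame(electrodes), nrow(electrodes) >= 1)
  defaults <- list(prob = prob, latency_ms = latency_ms, amplitude = amplitude,
                   sigmoid_mid_ma = sigmoid_mid_ma,
                   sigmoid_slope_ma = sigmoid_slope_ma,
                   gain_w = gain_w, gain_nrem = gain_nrem, gain_rem = gain_rem)
  if (is.null(connections)) {
    connections <- data.frame(from = character(), to = character(),
                              stringsAsFactors = FALSE)
  }
  connections <- as.data.frame(connections, stringsAsFactors = FALSE)
  if (nrow(connections)) {
    stopifnot(all(c("from", "to") %in% names(connections)))
    for (f in names(defaults)) {
      if (is.null(connections[[f]])) connections[[f]] <- defaults[[f]]
    }
    unknown <- setdiff(c(connections$from, connections$to), electrodes$name)
    if (length(unknown))
      stop("connections reference unknown electrodes: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    if (any(connections$from == connections$to))
      stop("self-connections are not allowed", call. = FALSE)
    if (any(connections$prob < 0 | connections$prob > 1))
      stop("true probabilities must lie in [0, 1]", call. = FALSE)
    if (any(!is.finite(connections$latency_ms) | connections$latency_ms <= 0))
      stop("latencies must be positive and finite", call. = FALSE)
  } else {
    for (f in names(defaults)) connections[[f]] <- numeric(0)
  }
  structure(list(electrodes = electrodes, connections = connections,
                 distances = electrode_distances(electrodes)),
            class = "gt_network")
}

# intensity sigmoid normalised to 1 at the 3 mA mapping intensity
.intensity_gain <- function(intensity_ma, mid, slope) {
  pmin(1, plogis((intensity_ma - mid) / slope) / plogis((3 - mid) / slope))
}

# collapse a 5-state vigilance label to the gain group used by the generator
.gain_group <- function(state) {
  out <- rep("W", length(state))
  out[state %in% c("N1", "N2", "N3")] <- "NREM"
  out[state == "R"] <- "REM"
  out
}

#' Planted-partition inter-areal incidence matrix
#'
#' Generates a symmetric areas-by-areas connection-incidence matrix (percent
#' of participants in which a connection between two areas was found) with a
#' planted community structure: within-community incidences are drawn with
#' probability `p_within` per pseudo-participant, between-community with
#' `p_between`.
#'
#' @param partition named integer/character vector mapping each area to its
#'   planted community.
#' @param p_within,p_between per-participant connection probabilities,
#'   `p_within > p_between`, both in `[0, 1]`.
#' @param n_participants pseudo-cohort size over which incidence (in %) is
#'   accumulated.
#' @param seed integer seed.
#'
#' @return symmetric numeric matrix (percent incidence), zero diagonal,
#'   dimnames = area names, with the planted partition attached as
#'   `attr(, "partition")`.
#' @export
make_incidence_matrix <- function(partition, p_within = 0.9, p_between = 0.05,
                                  n_participants = 100, seed = 1) {
  if (any(c(p_within, p_between) < 0 | c(p_within, p_between) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p_within < p_between)
    stop("p_within must be >= p_between", call. = FALSE)
  areas <- names(partition)
  if (is.null(areas)) areas <- paste0("area", seq_along(partition))
  k <- length(partition)
  m <- matrix(0, k, k, dimnames = list(areas, areas))
  .with_seed(seed, {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p <- if (partition[i] == partition[j]) p_within else p_between
        m[i, j] <- m[j, i] <- 100 * rbinom(1, n_participants, p) / n_participants
      }
    }
  })
  attr(m, "partition") <- partition
  m
}
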