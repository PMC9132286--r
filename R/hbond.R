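#' Detect geometric hydrogen bonds in one conformation
#'
#' A bond is reported iff (i) the heavy-donor-to-acceptor distance is at most
#' `d_max` and (ii) the donor--H...acceptor angle, measured at the hydrogen
#' (D-H-A), is at least `angle_min`; both criteria inclusive at the boundary.
#' Intra-residue pairs are excluded.
#'
#' @param model a [structure_model()] with hydrogens.
#' @param topology an `hbond_topology` ([build_hbond_topology()]).
#' @param d_max maximum donor-acceptor distance (Angstrom).
#' @param angle_min minimum D-H-A angle (degrees).
#' @return data.frame with one row per observation: `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `donor_resno`, `acceptor_resno`, `distance`,
#'   `angle`.
#' @export
detect_hbonds_frame <- function(model, topology, d_max = 3.5,
                                angle_min = 120) {
  stopifnot(inherits(model, "structure_model"),
            inherits(topology, "hbond_topology"))
  xyz <- coords_of(model$xyz)
  resno <- model$atom$resno
  don <- topology$donors
  acc <- topology$acceptors
  out <- list()
  for (k in seq_len(nrow(don))) {
    D <- don$heavy[k]; H <- don$hydrogen[k]
    cand <- acc[acc != D & resno[acc] != resno[D]]
    if (!length(cand)) next
    dv <- sweep(xyz[cand, , drop = FALSE], 2L, xyz[D, ])
    dist <- sqrt(rowSums(dv^2))
    near <- dist <= d_max
    if (!any(near)) next
    cand <- cand[near]; dist <- dist[near]
    hd <- xyz[D, ] - xyz[H, ]
    ha <- sweep(xyz[cand, , drop = FALSE], 2L, xyz[H, ])
    cosang <- (ha %*% hd) / (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok <- ang >= angle_min
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      donor = D, hydrogen = H, acceptor = cand[ok],
      donor_resno = resno[D], acceptor_resno = resno[cand[ok]],
      distance = dist[ok], angle = ang[ok])
  }
  if (!length(out))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), donor_resno = integer(),
                      acceptor_resno = integer(), distance = numeric(),
                      angle = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' For every (donor heavy atom, acceptor atom) pair, occupancy is the
#' percentage of frames in which the pair satisfies the geometric criteria.
#' Alternative hydrogens of one donor count as a single bond per frame (no
#' double counting). Each pair is also labelled with its strength class
#' ([classify_strength()]).
#'
#' @param ens an [ensemble()] (raw coordinates; hydrogen-bond geometry is
#'   rigid-motion invariant, so no superposition is applied).
#' @param topology an `hbond_topology` built on the shared topology.
#' @param d_max,angle_min geometric criteria, see [detect_hbonds_frame()].
#' @param min_occupancy report only pairs with occupancy strictly above this
#'   percentage (default 0: report all observed pairs).
#' @return data.frame of class `hbond_stats`: `donor` / `acceptor` atom
#'   indices, `donor_resno`, `donor_atom`, `acceptor_resno`, `acceptor_atom`,
#'   `occupancy` (percent), `strength`.
#' @export
hbond_occupancy <- function(ens, topology, d_max = 3.5, angle_min = 120,
                            min_occupancy = 0) {
  stopifnot(inherits(ens, "ensemble"))
  nf <- n_frames(ens)
  if (nf < 1L) stop("ensemble has no frames")
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    obs <- detect_hbonds_frame(get_frame(ens, i), topology, d_max, angle_min)
    if (!nrow(obs)) next
    pairs <- unique(paste(obs$donor, obs$acceptor))  # collapse alt hydrogens
    for (p in pairs) {
      n <- if (is.null(counts[[p]])) 0L else counts[[p]]
      counts[[p]] <- n + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys))
    return(empty_hbond_stats())
  dd <- do.call(rbind, lapply(keys, function(k) {
    ij <- as.integer(strsplit(k, " ")[[1L]])
    data.frame(donor = ij[1L], acceptor = ij[2L],
               n_frames_present = counts[[k]])
  }))
  a <- ens$atom
  occ <- 100 * dd$n_frames_present / nf
  out <- data.frame(donor = dd$donor, acceptor = dd$acceptor,
                    donor_resno = a$resno[dd$donor],
                    donor_atom = a$name[dd$donor],
                    acceptor_resno = a$resno[dd$acceptor],
                    acceptor_atom = a$name[dd$acceptor],
                    occupancy = occ,
                    strength = classify_strength(occ),
                    stringsAsFactors = FALSE)
  out <- out[out$occupancy > min_occupancy, , drop = FALSE]
  out <- out[order(out$donor_resno, out$acceptor_resno, out$donor_atom), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_stats", "data.frame")
  out
}

empty_hbond_stats <- function() {
  out <- data.frame(donor = integer(), acceptor = integer(),
                    donor_resno = integer(), donor_atom = character(),
                    acceptor_resno = integer(), acceptor_atom = character(),
                    occupancy = numeric(), strength = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("hbond_stats", "data.frame")
  out
}

#' Classify hydrogen-bond strength from occupancy
#'
#' Four occupancy levels: strong (> 75 percent), medium (75 >= occ > 50),
#' weak (50 >= occ > 25), very weak (25 >= occ > 10). Occupancies of 10
#' percent or below are `"unreported"` (below the reporting floor).
#'
#' @param occupancy numeric vector of occupancies in `[0, 100]`.
#' @return character vector: `"strong"`, `"medium"`, `"weak"`,
#'   `"very_weak"` or `"unreported"`.
#' @export
classify_strength <- function(occupancy) {
  if (any(!is.finite(occupancy)) || any(occupancy < 0 | occupancy > 100))
    stop("occupancy must lie in [0, 100]")
  ifelse(occupancy > 75, "strong",
  ifelse(occupancy > 50, "medium",
  ifelse(occupancy > 25, "weak",
  ifelse(occupancy > 10, "very_weak", "unreported"))))
}

#' Count hydrogen bonds of a flexible region by strength class
#'
#' Counts unique donor/acceptor pairs with at least one partner residue
#' inside the region; the other partner is unrestricted by default (the
#' design shell already limited neighbours), or can be restricted to
#' residues within `neighbor_cutoff` Angstrom of the region in a reference
#' frame.
#'
#' @param stats an `hbond_stats` table ([hbond_occupancy()]).
#' @param region one row of a `flexible_regions` table.
#' @param neighbor_cutoff optional distance cutoff (Angstrom) restricting the
#'   partner residue; requires `model`.
#' @param model reference [structure_model()] used for the neighbour
#'   distance.
#' @return named integer vector `c(strong, medium, weak, very_weak)`.
#' @export
region_hbond_summary <- function(stats, region, neighbor_cutoff = NULL,
                                 model = NULL) {
  rng <- seq.int(region$start_residue[1L], region$end_residue[1L])
  res <- c("strong" = 0L, "medium" = 0L, "weak" = 0L, "very_weak" = 0L)
  if (!nrow(stats)) {
    attr(res, "region_id") <- region$region_id[1L]
    return(res)
  }
  din <- stats$donor_resno %in% rng
  ain <- stats$acceptor_resno %in% rng
  keep <- din | ain
  if (!is.null(neighbor_cutoff)) {
    if (is.null(model))
      stop("neighbor_cutoff requires a reference model")
    partner <- ifelse(din, stats$acceptor_resno, stats$donor_resno)
    near <- vapply(unique(partner), function(r) {
      min(vapply(rng, function(q)
        residue_min_distance(model, r, q), numeric(1))) <= neighbor_cutoff
    }, logical(1))
    keep <- keep & near[match(partner, unique(partner))]
  }
  s <- stats$strength[keep]
  for (cls in names(res)) res[cls] <- sum(s == cls)
  attr(res, "region_id") <- region$region_id[1L]
  res
}

residue_min_distance <- function(model, r1, r2) {
  xyz <- coords_of(model$xyz)
  i <- which(model$atom$resno == r1); j <- which(model$atom$resno == r2)
  if (!length(i) || !length(j)) return(Inf)
  a <- xyz[i, , drop = FALSE]; b <- xyz[j, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Difference between two region hydrogen-bond summaries (mutant - wild type)
#'
#' @param wildtype,mutant summaries from [region_hbond_summary()] for the
#'   same region.
#' @return named numeric vector of per-class deltas plus `total`.
#' @export
diff_hbond_reports <- function(wildtype, mutant) {
  rw <- attr(wildtype, "region_id"); rm_ <- attr(mutant, "region_id")
  if (!is.null(rw) && !is.null(rm_) && !identical(rw, rm_))
    stop("summaries come from different regions: ", rw, " vs ", rm_)
  cls <- c("strong", "medium", "weak", "very_weak")
  d <- as.numeric(mutant[cls]) - as.numeric(wildtype[cls])
  c(setNames(d, cls), total = sum(d))
}
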