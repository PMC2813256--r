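#' Ligand panel of the RAW 264.7 screens
#'
#' Abbreviations of the 22 ligands used in the AfCS single- and two-ligand
#' phosphoprotein screens. Used as the default panel of the synthetic
#' generator.
#'
#' @format Character vector of 22 ligand codes.
#' @export
afcs_ligands <- c(
  "2MA", "848", "C5A", "GMF", "I04", "I06", "I10", "I1B", "IFA", "IFB",
  "IFG", "ISO", "LPA", "LPS", "MCF", "P2C", "P3C", "PAF", "PGE", "S1P",
  "TGF", "UDP"
)

#' Generate a ground-truth signed linear signaling network
#'
#' Draws a sparse square coefficient matrix `B_true` describing a lag-1 linear
#' propagation rule in log2 fold-change space, `x[t] = B_true %*% x[t-1] + noise`,
#' together with per-ligand stimulus vectors. Diagonal (self-regulation) terms
#' are strictly positive and dominate every off-diagonal entry in their row,
#' reflecting the strong self-correlation typical of phosphoprotein screens;
#' off-diagonal "crosstalk" edges get random positions and signs. The spectral
#' radius of `B_true` is kept at or below 1 so trajectories do not explode.
#'
#' @param n_proteins Number of phosphoproteins (nodes), at least 2.
#' @param cross_density Fraction of possible off-diagonal entries that are
#'   nonzero; the realised count is exactly
#'   `round(cross_density * n_proteins * (n_proteins - 1))`.
#' @param seed Integer RNG seed; the result is a deterministic function of it.
#' @param ligands Ligand panel for the stimulus map (default [afcs_ligands]).
#' @param noise_sd Standard deviation of the additive log2 measurement noise
#'   the simulator will apply (stored here so a truth object fully specifies a
#'   simulation). Default 0.2 log2 units, a realistic western-blot-scale noise
#'   floor.
#' @param diag_range,cross_range Ranges for the magnitudes of diagonal and
#'   off-diagonal coefficients. Defaults keep self terms (0.5-0.7) above
#'   crosstalk terms (0.3-0.45).
#' @param offtarget_density Probability of a weak secondary (off-target)
#'   effect of a ligand on a non-primary protein (default 0.1). Each ligand
#'   additionally has one strong primary-target effect, assigned round-robin
#'   so every protein is some ligand's primary target when the panel is
#'   large enough; this mirrors screens in which each ligand chiefly
#'   activates its own receptor pathway, giving weakly cross-correlated
#'   inputs and a near-diagonal lagged correlation map.
#' @param primary_range Magnitude range of primary-target log2 effects
#'   (default 0.8-1.6, random sign).
#' @param offtarget_sd Standard deviation of off-target log2 effects
#'   (default 0.15).
#'
#' @return An object of class `phos_truth`: a list with `proteins`, `B_true`
#'   (rows = outputs at `t_k`, cols = inputs at `t_{k-1}`), `stimulus_map`
#'   (ligands x proteins matrix of initial log2 perturbations), `noise_sd`
#'   and `seed`.
#' @seealso [simulate_screen()], [truth_edges()]
#' @export
#' @examples
#' truth <- generate_ground_truth(5, cross_density = 0.2, seed = 1)
#' sum(truth$B_true[row(truth$B_true) != col(truth$B_true)] != 0) # exactly 4
generate_ground_truth <- function(n_proteins, cross_density = 0.1, seed = 1,
                                  ligands = afcs_ligands, noise_sd = 0.2,
                                  diag_range = c(0.5, 0.7),
                                  cross_range = c(0.3, 0.45),
                                  offtarget_density = 0.1,
                                  primary_range = c(0.8, 1.6),
                                  offtarget_sd = 0.15) {
  check_number(n_proteins, "n_proteins", lower = 2, integerish = TRUE)
  check_number(cross_density, "cross_density", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  stopifnot(is.character(ligands), length(ligands) >= 1)
  local_seed_if(seed)

  n <- as.integer(n_proteins)
  proteins <- sprintf("PP%02d", seq_len(n))
  n_cross <- round(cross_density * n * (n - 1))
  off_idx <- which(row(diag(n)) != col(diag(n)))

  draw_B <- function() {
    B <- matrix(0, n, n, dimnames = list(proteins, proteins))
    diag(B) <- runif(n, diag_range[1], diag_range[2])
    if (n_cross > 0) {
      pos <- sample(off_idx, n_cross)
      B[pos] <- sample(c(-1, 1), n_cross, replace = TRUE) *
        runif(n_cross, cross_range[1], cross_range[2])
    }
    B
  }
  # redraw until the spectral radius is admissible; deterministic under seed
  B <- draw_B()
  tries <- 1L
  while (max(Mod(eigen(B, only.values = TRUE)$values)) > 1 && tries < 200L) {
    B <- draw_B()
    tries <- tries + 1L
  }
  if (max(Mod(eigen(B, only.values = TRUE)$values)) > 1) {
    abort("Could not draw a stable coefficient matrix; lower `cross_density` or `cross_range`.")
  }

  n_lig <- length(ligands)
  S <- matrix(
    rnorm(n_lig * n, sd = offtarget_sd) * (runif(n_lig * n) < offtarget_density),
    nrow = n_lig, ncol = n, dimnames = list(ligands, proteins)
  )
  # one strong primary target per ligand, round-robin over proteins
  primary <- rep_len(sample.int(n), n_lig)
  S[cbind(seq_len(n_lig), primary)] <-
    sample(c(-1, 1), n_lig, replace = TRUE) *
    runif(n_lig, primary_range[1], primary_range[2])

  structure(
    list(proteins = proteins, B_true = B, stimulus_map = S,
         noise_sd = noise_sd, seed = seed),
    class = "phos_truth"
  )
}

#' @export
print.phos_truth <- function(x, ...) {
  n <- length(x$proteins)
  cat(sprintf(
    "<phos_truth> %d proteins, %d cross edges, %d ligands, noise_sd = %g\n",
    n, sum(x$B_true[row(x$B_true) != col(x$B_true)] != 0),
    nrow(x$stimulus_map), x$noise_sd
  ))
  invisible(x)
}

#' Ground-truth crosstalk edges as a tibble
#'
#' Off-diagonal nonzero coefficients of `B_true` as a signed edge list
#' (`source` regulates `target`), the reference against which recovered
#' networks are scored.
#'
#' @param truth A [generate_ground_truth()] object.
#' @return Tibble with columns `source`, `target`, `sign`, `weight`.
#' @export
truth_edges <- function(truth) {
  stopifnot(inherits(truth, "phos_truth"))
  B <- truth$B_true
  idx <- which(B != 0 & row(B) != col(B), arr.ind = TRUE)
  tibble::tibble(
    source = truth$proteins[idx[, "col"]],   # column = input at t-1
    target = truth$proteins[idx[, "row"]],   # row    = output at t
    sign = as.integer(sign(B[idx])),
    weight = B[idx]
  ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' Write ground-truth edges as TSV
#' @param truth A `phos_truth` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_edges <- function(truth, path) {
  readr::write_tsv(truth_edges(truth), path)
  invisible(path)
}

#' Simulate a single-/double-ligand phosphoprotein screen
#'
#' Emulates an AfCS-style fold-change screen: conditions stimulate the system
#' with one or two ligands; the log2 state at the first post-stimulus time is
#' the sum of the ligand stimulus vectors plus noise; each later grid time
#' advances the state by one application of `B_true` plus noise; reported
#' values are fold changes `2^x` with the t = 0 baseline identically 1.
#' Double-ligand effects are additive in log2 stimulus space by default; an
#' optional interaction term (`interaction_sd`) perturbs dual conditions.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param conditions Optional list of character vectors (each of length 1 or
#'   2) naming the ligand set of every condition. When `NULL`, the default
#'   design uses all single-ligand conditions followed by randomly sampled
#'   distinct ligand pairs up to `n_conditions` (251 by default, the size of
#'   the combined AfCS single- and two-ligand screens).
#' @param n_conditions Number of conditions when `conditions` is `NULL`.
#' @param replicates Either a single replicate count, a vector of
#'   per-condition counts, or `NULL` for the default 50/50 mix of duplicates
#'   and triplicates.
#' @param timepoints Time grid in minutes; must contain 0 and at least two
#'   post-stimulus times. Default `c(0, 1, 3, 10, 30)`.
#' @param seed Integer RNG seed.
#' @param interaction_sd Standard deviation of an optional extra log2
#'   perturbation applied to double-ligand conditions (default 0: purely
#'   additive combination).
#'
#' @return A tibble of class `phos_screen` in the long screen dialect:
#'   columns `experiment_id`, `ligands` (codes joined by `+`), `replicate`,
#'   `time_min`, `protein`, `fold_change`.
#' @export
#' @examples
#' truth <- generate_ground_truth(4, 0.2, seed = 1, ligands = c("LPS", "PGE"))
#' scr <- simulate_screen(truth, n_conditions = 3, timepoints = c(0, 1, 3),
#'                        seed = 2)
#' dplyr::count(scr, time_min)
simulate_screen <- function(truth, conditions = NULL, n_conditions = 251,
                            replicates = NULL,
                            timepoints = c(0, 1, 3, 10, 30), seed = 1,
                            interaction_sd = 0) {
  stopifnot(inherits(truth, "phos_truth"))
  check_number(interaction_sd, "interaction_sd", lower = 0)
  if (truth$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  timepoints <- sort(unique(as.numeric(timepoints)))
  if (!0 %in% timepoints || length(timepoints) < 3) {
    abort("`timepoints` must include 0 and at least two post-stimulus times.")
  }
  local_seed_if(seed)

  ligs <- rownames(truth$stimulus_map)
  if (is.null(conditions)) {
    check_number(n_conditions, "n_conditions", lower = 1, integerish = TRUE)
    singles <- as.list(ligs)
    n_extra <- n_conditions - length(singles)
    if (n_extra < 0) {
      conditions <- singles[seq_len(n_conditions)]
    } else {
      pairs <- combn(ligs, 2, simplify = FALSE)
      if (n_extra > length(pairs)) {
        abort("`n_conditions` exceeds the number of distinct ligand sets.")
      }
      conditions <- c(singles, sample(pairs, n_extra))
    }
  }
  bad <- !vapply(conditions, function(l) {
    length(l) %in% 1:2 && all(l %in% ligs)
  }, logical(1))
  if (any(bad)) {
    abort(sprintf(
      "Condition(s) %s use unknown ligands or have size outside 1-2.",
      paste(which(bad), collapse = ", ")
    ))
  }

  n_cond <- length(conditions)
  if (is.null(replicates)) {
    replicates <- sample(rep_len(c(2L, 3L), n_cond))
  } else if (length(replicates) == 1L) {
    replicates <- rep_len(as.integer(replicates), n_cond)
  } else if (length(replicates) != n_cond) {
    abort("`replicates` must have length 1 or one entry per condition.")
  }

  n <- length(truth$proteins)
  post <- timepoints[timepoints > 0]
  sdn <- truth$noise_sd

  rows <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    lig_set <- conditions[[ci]]
    stim <- colSums(truth$stimulus_map[lig_set, , drop = FALSE])
    reps <- replicates[ci]
    per_rep <- vector("list", reps)
    for (r in seq_len(reps)) {
      x <- stim + rnorm(n, sd = sdn)
      if (length(lig_set) == 2 && interaction_sd > 0) {
        x <- x + rnorm(n, sd = interaction_sd)
      }
      states <- matrix(0, length(timepoints), n,
                       dimnames = list(NULL, truth$proteins))
      states[match(post[1], timepoints), ] <- x
      for (k in seq_along(post)[-1]) {
        x <- drop(truth$B_true %*% x) + rnorm(n, sd = sdn)
        states[match(post[k], timepoints), ] <- x
      }
      per_rep[[r]] <- tibble::tibble(
        replicate = r,
        time_min = rep(timepoints, each = n),
        protein = rep(truth$proteins, length(timepoints)),
        fold_change = 2^as.vector(t(states))
      )
    }
    rows[[ci]] <- dplyr::bind_rows(per_rep) |>
      dplyr::mutate(
        experiment_id = sprintf("E%04d", ci),
        ligands = paste(lig_set, collapse = "+"),
        .before = 1
      )
  }
  out <- dplyr::bind_rows(rows)
  as_screen(out)
}
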