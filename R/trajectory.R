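#' Trajectory container
#'
#' @param frames numeric array of dimension `n_frames x n_beads x 3` (A).
#' @param times frame times (ps), strictly increasing.
#' @param energies optional per-frame energy data.frame.
#' @return Object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, times, energies = NULL) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3 || dim(frames)[3] != 3)
    stop("frames must be an n_frames x n_beads x 3 array")
  if (dim(frames)[1] != length(times))
    stop("times length must match the number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times),
                 energies = energies),
            class = "cg_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj a `cg_trajectory`.
#' @param i frame index.
#' @return N x 3 matrix (A).
#' @export
traj_frame <- function(traj, i) {
  matrix(traj$frames[i, , ], ncol = 3)
}

#' Concatenate trajectories
#' @param ... `cg_trajectory` objects over the same beads, in time order.
#' @return A single `cg_trajectory`; energies are row-bound when all parts
#'   carry them.
#' @export
concat_trajectories <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "cg_trajectory"))
    parts <- parts[[1]]
  if (length(parts) == 0) stop("nothing to concatenate")
  nb <- dim(parts[[1]]$frames)[2]
  total <- sum(vapply(parts, n_frames, integer(1)))
  frames <- array(NA_real_, c(total, nb, 3))
  times <- numeric(total)
  at <- 0
  for (p in parts) {
    nf <- n_frames(p)
    frames[at + seq_len(nf), , ] <- p$frames
    times[at + seq_len(nf)] <- p$times
    at <- at + nf
  }
  energies <- NULL
  if (all(vapply(parts, function(p) !is.null(p$energies), logical(1))))
    energies <- do.call(rbind, lapply(parts, `[[`, "energies"))
  cg_trajectory(frames, times, energies)
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", n_frames(x), " frames x ", dim(x$frames)[2],
      " beads, t = [", signif(min(x$times), 6), ", ",
      signif(max(x$times), 6), "] ps\n", sep = "")
  invisible(x)
}
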