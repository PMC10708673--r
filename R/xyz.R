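## Extended-XYZ trajectory I/O. Per frame: a bead-count line, a comment
## line `time=<tau> seed=<int>`, then one line per bead
## `<tag> <x> <y> <z> <charge>` with tag C/N/P for neutral/negative/
## positive beads and coordinates printed with 6 decimals. read(write(T))
## reproduces the text representation bit-exactly.

#' Write a trajectory in extended-XYZ format
#'
#' @param traj a `trajectory` (or a single `conformation`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "conformation")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"))
  seed <- traj$metadata$seed
  if (is.null(seed)) seed <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    n <- nrow(f$positions)
    tag <- ifelse(f$charges > 0, "P", ifelse(f$charges < 0, "N", "C"))
    writeLines(c(sprintf("%d", n),
                 sprintf("time=%.6f seed=%d", f$time, as.integer(seed)),
                 sprintf("%s %.6f %.6f %.6f %d", tag,
                         f$positions[, 1], f$positions[, 2],
                         f$positions[, 3], as.integer(f$charges))),
               con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Malformed input is reported with the offending line number and frame.
#'
#' @param path file path.
#' @return A `trajectory`; the seed of the first frame is kept in the
#'   metadata.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  frame_no <- 0L
  seed <- NULL
  while (i <= length(lines)) {
    frame_no <- frame_no + 1L
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n < 1)
      stop(sprintf("parse error at line %d (frame %d): invalid bead count '%s'",
                   i, frame_no, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("parse error: truncated frame %d starting at line %d (%d atom lines expected)",
                   frame_no, i, n))
    cm <- regmatches(lines[i + 1L],
                     regexec("^time=([-0-9.eE+]+) seed=(-?[0-9]+)$", lines[i + 1L]))[[1]]
    if (length(cm) != 3L)
      stop(sprintf("parse error at line %d (frame %d): bad comment line", i + 1L, frame_no))
    tm <- as.numeric(cm[2])
    if (is.null(seed)) seed <- as.integer(cm[3])
    atoms <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(atoms, " ", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad))
      stop(sprintf("parse error at line %d (frame %d): expected 5 fields",
                   i + 1L + bad[1], frame_no))
    m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
    if (!all(m[, 1] %in% c("C", "N", "P")))
      stop(sprintf("parse error in frame %d: unknown atom tag", frame_no))
    pos <- matrix(as.numeric(m[, 2:4]), ncol = 3)
    z <- as.numeric(m[, 5])
    if (any(!is.finite(pos)) || any(is.na(z)))
      stop(sprintf("parse error in frame %d: non-numeric coordinate or charge",
                   frame_no))
    exp_tag <- ifelse(z > 0, "P", ifelse(z < 0, "N", "C"))
    if (!all(m[, 1] == exp_tag))
      stop(sprintf("parse error in frame %d: tag/charge mismatch", frame_no))
    frames[[frame_no]] <- conformation(pos, z, time = tm)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("empty trajectory file")
  trajectory(frames, metadata = list(seed = seed, source = path))
}
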