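# Extended-XYZ-dialect trajectory I/O. Each frame:
#   line 1: atom count
#   line 2: comment carrying "time_ns=<t> box=<Lx> <Ly> <Lz>"
#   then one "element x y z" line per atom.
# Atom roles, charges and the ring flag live in a sidecar CSV
# (atom_index, role, charge, ring_flag), constant across frames.

parse_xyz_comment <- function(line, lineno) {
  tm <- regmatches(line, regexec("time_ns=([-0-9.eE+]+)", line))[[1]]
  bx <- regmatches(line, regexec(
    "box=([-0-9.eE+]+)[ ,]+([-0-9.eE+]+)[ ,]+([-0-9.eE+]+)", line))[[1]]
  if (length(tm) < 2 || length(bx) < 4)
    stop("line ", lineno, ": malformed frame comment (need time_ns= and box=)")
  rest <- sub(".*box=[-0-9.eE+]+[ ,]+[-0-9.eE+]+[ ,]+[-0-9.eE+]+", "", line)
  if (grepl("[-0-9.eE+]", gsub("[ ,]", "", rest)))
    stop("line ", lineno,
         ": unsupported geometry: box must have exactly 3 edge lengths")
  list(time = as.numeric(tm[2]), box = as.numeric(bx[2:4]))
}

#' Read a trajectory from extended-XYZ + roles sidecar
#'
#' @param xyz_path Path to the XYZ-dialect trajectory file.
#' @param roles_path Path to the sidecar CSV with columns `atom_index`,
#'   `role`, `charge`, `ring_flag`.
#' @return List of [traj_frame()] objects.
#' @export
read_xyz_trajectory <- function(xyz_path, roles_path) {
  if (!file.exists(xyz_path)) stop("input file not found: ", xyz_path)
  if (!file.exists(roles_path)) stop("input file not found: ", roles_path)
  roles_df <- utils::read.csv(roles_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("atom_index", "role", "charge", "ring_flag"),
                  names(roles_df))
  if (length(miss))
    stop(roles_path, ": missing columns: ", paste(miss, collapse = ", "))
  roles_df <- roles_df[order(roles_df$atom_index), ]
  lines <- readLines(xyz_path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nat) || nat <= 0)
      stop(xyz_path, " line ", i, ": expected an atom count, got '",
           lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop(xyz_path, " line ", i, ": truncated frame (", nat,
           " atoms declared)")
    hdr <- parse_xyz_comment(lines[i + 1L], i + 1L)
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "[ \t]+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop(xyz_path, " line ", i + 1L + bad[1], ": malformed atom line")
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      stop(xyz_path, ": non-numeric coordinates in frame starting line ", i)
    if (nat != nrow(roles_df))
      stop(xyz_path, " line ", i, ": frame has ", nat,
           " atoms but roles sidecar describes ", nrow(roles_df))
    frames[[length(frames) + 1L]] <- traj_frame(
      time = hdr$time, box = hdr$box, coords = xyz,
      roles = roles_df$role, charges = roles_df$charge,
      ring_atoms = roles_df$atom_index[roles_df$ring_flag == 1],
      elements = el)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop(xyz_path, ": no frames found")
  frames
}

#' Write a trajectory to extended-XYZ + roles sidecar
#'
#' Inverse of [read_xyz_trajectory()]; coordinates are serialized with 17
#' significant digits so a round-trip is lossless.
#'
#' @param trajectory List of [traj_frame()] objects sharing one atom layout.
#' @param xyz_path Output XYZ path.
#' @param roles_path Output sidecar CSV path.
#' @return `xyz_path`, invisibly.
#' @export
write_xyz_trajectory <- function(trajectory, xyz_path, roles_path) {
  stopifnot(length(trajectory) >= 1,
            all(vapply(trajectory, inherits, logical(1), "traj_frame")))
  f1 <- trajectory[[1]]
  ring_flag <- as.integer(seq_len(nrow(f1$coords)) %in% f1$ring_atoms)
  roles_df <- data.frame(atom_index = seq_len(nrow(f1$coords)),
                         role = f1$roles,
                         charge = fmt_num(f1$charges),
                         ring_flag = ring_flag)
  utils::write.csv(roles_df, roles_path, row.names = FALSE, quote = FALSE)
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (fr in trajectory) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("time_ns=%s box=%s %s %s", fmt_num(fr$time),
                       fmt_num(fr$box[1]), fmt_num(fr$box[2]),
                       fmt_num(fr$box[3])), con)
    writeLines(sprintf("%s %s %s %s", fr$elements,
                       fmt_num(fr$coords[, 1]), fmt_num(fr$coords[, 2]),
                       fmt_num(fr$coords[, 3])), con)
  }
  invisible(xyz_path)
}
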