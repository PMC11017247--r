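## File formats: GRO and XYZ structures, Gromacs-dialect topologies with
## exact round-tripping of the parameter set, time-series CSV, and the
## structured-text run configuration.

#' Write a GRO structure file
#'
#' Fixed-width Gromacs GRO dialect: positions in nm at 3-decimal precision,
#' velocities in nm/ps at 4 decimals, residue SOL with atoms OW/HW1/HW2.
#' The virtual M site is never written; it is regenerated from the
#' virtual-site rule on demand (see \code{\link{msitePositions}}).
#'
#' @param state a \code{SystemState}
#' @param path output file
#' @param title header line
#' @param velocities include the velocity columns?
#' @return \code{path}, invisibly
#' @export
writeGro <- function(state, path, title = "rwail water", velocities = TRUE) {
  n <- nrow(state@positions)
  lines <- c(sprintf("%s, t= %.5f", title, state@time), sprintf("%5d", n))
  mol <- state@molecule
  nm <- state@siteNames
  p <- state@positions
  v <- state@velocities
  fmt <- if (velocities) "%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f"
         else "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"
  for (i in seq_len(n)) {
    args <- list(mol[i] %% 100000L, "SOL", nm[i], i %% 100000L,
                 p[i, 1], p[i, 2], p[i, 3])
    if (velocities) args <- c(args, list(v[i, 1], v[i, 2], v[i, 3]))
    lines <- c(lines, do.call(sprintf, c(fmt, args)))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", state@box[1],
                            state@box[2], state@box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO structure file
#'
#' @param path GRO file with 3 physical sites per water molecule
#' @return a \code{SystemState}
#' @export
readGro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file: line 2 is not an atom count")
  if (length(lines) < n + 3)
    stop("malformed GRO file: expected ", n + 3, " lines, found ",
         length(lines))
  num <- function(s, i) {
    x <- suppressWarnings(as.numeric(s))
    if (any(is.na(x)))
      stop("malformed GRO record at line ", i, ": '", s[is.na(x)][1], "'")
    x
  }
  pos <- matrix(0, n, 3)
  vel <- matrix(0, n, 3)
  mol <- integer(n)
  nms <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[i + 2]
    mol[i] <- as.integer(num(substr(ln, 1, 5), i + 2))
    nms[i] <- trimws(substr(ln, 11, 15))
    pos[i, ] <- num(c(substr(ln, 21, 28), substr(ln, 29, 36),
                      substr(ln, 37, 44)), i + 2)
    if (nchar(ln) >= 68)
      vel[i, ] <- num(c(substr(ln, 45, 52), substr(ln, 53, 60),
                        substr(ln, 61, 68)), i + 2)
  }
  box <- num(strsplit(trimws(lines[n + 3]), "\\s+")[[1]][1:3], n + 3)
  if (n %% 3 != 0)
    stop("expected 3 physical sites per molecule, found ", n, " atoms")
  new("SystemState", box = box, positions = pos, velocities = vel,
      molecule = rep(seq_len(n %/% 3L), each = 3L),
      siteNames = nms, time = 0, wrapped = TRUE,
      metadata = list(source = path))
}

#' Virtual-site positions of a state
#'
#' @param state a \code{SystemState}
#' @param params a \code{ForceFieldParameters}
#' @return n_molecules x 3 matrix of M positions (nm)
#' @export
msitePositions <- function(state, params) {
  n <- nMolecules(state)
  p <- state@positions
  iO <- 3 * (seq_len(n) - 1) + 1
  (1 - 2 * params@a) * p[iO, , drop = FALSE] +
    params@a * (p[iO + 1, , drop = FALSE] + p[iO + 2, , drop = FALSE])
}

#' Write / read XYZ coordinates
#'
#' Plain XYZ in Angstrom; the comment line carries the box lengths
#' (Angstrom) so the round trip preserves periodicity.  GRO<->XYZ
#' conversion is exactly the factor 10.
#'
#' @param state a \code{SystemState}
#' @param path file path
#' @return \code{path} (writer) / a \code{SystemState} (reader)
#' @export
writeXyz <- function(state, path) {
  n <- nrow(state@positions)
  pA <- state@positions * 10
  el <- ifelse(grepl("^O", state@siteNames), "O", "H")
  lines <- c(sprintf("%d", n),
             sprintf("box %.10g %.10g %.10g", state@box[1] * 10,
                     state@box[2] * 10, state@box[3] * 10),
             sprintf("%-2s %15.8f %15.8f %15.8f", el, pA[, 1], pA[, 2],
                     pA[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeXyz
#' @param box box lengths (nm) when the comment line does not carry them
#' @export
readXyz <- function(path, box = NULL) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  cm <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (is.null(box)) {
    if (length(cm) >= 4 && cm[1] == "box")
      box <- as.numeric(cm[2:4]) / 10
    else stop("no box in the XYZ comment line; pass 'box' explicitly")
  }
  rec <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  el <- vapply(rec, `[`, character(1), 1)
  pos <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3))) / 10
  if (any(is.na(pos))) stop("malformed XYZ coordinate record")
  if (n %% 3 != 0) stop("expected 3 physical sites per molecule")
  nmol <- n %/% 3L
  new("SystemState", box = box, positions = pos,
      velocities = matrix(0, n, 3),
      molecule = rep(seq_len(nmol), each = 3L),
      siteNames = rep(c("OW", "HW1", "HW2"), nmol),
      time = 0, wrapped = TRUE, metadata = list(source = path))
}

## --------------------------------------------------------------------------
## Gromacs topology dialect.
##
## The exponential O-O repulsion has no Lennard-Jones representation; the
## export uses the Buckingham route ([ defaults ] nbfunc 2) with
## A exp(-B r) - C6/r^6, which maps the model exactly.  The hydrogen-bond
## wall and the quartic bonds have no native directive; they are carried in
## machine-readable extension comments (';; rwail-extension ...') which a
## Gromacs run would realize as tabulated interactions.  Units in the files
## are the kJ/nm dialect; the reader inverts the writer exactly.

kJ <- 4.184

## dialect conversion factors, shared by writer and reader so the round
## trip divides by exactly the value it multiplied with; the reader rounds
## the back-conversion to 14 significant digits, which is exact for any
## parameter stated to that precision or less
dialect <- list(A = kJ, B = 10, C6 = kJ * 1e-6, A4 = kJ * 1e4,
                rc = 0.1, re = 0.1, k2 = kJ * 1e2, k3 = kJ * 1e3,
                k4 = kJ * 1e4, kTheta = kJ)
fromDialect <- function(x, f) signif(x / f, 14)

#' Export a Gromacs-dialect topology set
#'
#' Writes three files: \code{<prefix>.top} (system), \code{<prefix>_ff.itp}
#' (defaults + Buckingham atom types) and \code{<prefix>_mol.itp}
#' (moleculetype with the virtual site and either settles (rigid) or the
#' quartic-bond/harmonic-angle extension blocks (flexible)).  All values
#' are written at 17 significant digits so
#' \code{\link{readGromacsTopology}} recovers the parameter set bit-for-bit
#' after unit back-conversion.
#'
#' @param params a \code{ForceFieldParameters}
#' @param dir output directory
#' @param prefix file-name prefix
#' @return character vector of the three paths, invisibly
#' @export
writeGromacsTopology <- function(params, dir = ".", prefix = "rwail") {
  g <- function(x) sprintf("%.17g", x)
  rigid <- isRigid(params)
  ffPath <- file.path(dir, paste0(prefix, "_ff.itp"))
  molPath <- file.path(dir, paste0(prefix, "_mol.itp"))
  topPath <- file.path(dir, paste0(prefix, ".top"))
  writeLines(c(
    sprintf("; rWAIL %s force-field parameters (kJ, nm dialect)", params@variant),
    "; O-O repulsion is exponential: exported via the Buckingham route",
    "; (nbfunc 2): V = A exp(-B r) - C6 r^-6.",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    "  2      1         no        1.0     1.0",
    "",
    "[ atomtypes ]",
    "; name  mass      charge  ptype  A(kJ/mol)  B(1/nm)  C6(kJ nm^6/mol)",
    sprintf("  OW  %.6f  0.0  A  %s  %s  %s", 15.999,
            g(params@AOO * dialect$A), g(params@alpha * dialect$B),
            g(params@COO * dialect$C6)),
    sprintf("  HW  %.6f  %s  A  0  0  0", 1.008, g(params@qH)),
    sprintf("  MW  0.0  %s  D  0  0  0", g(params@qM)),
    "",
    sprintf(";; rwail-extension hb-wall A4_kJ_nm4 %s rc_nm %s",
            g(params@A4 * dialect$A4), g(params@rc * dialect$rc)),
    ";; (U_HB = A4 (r_MH - rc)^4 below rc; realized as a tabulated M-H term)"
  ), ffPath)
  mol <- c(
    sprintf("; rWAIL %s water molecule", params@variant),
    "[ moleculetype ]",
    "; name  nrexcl",
    "  SOL   2",
    "",
    "[ atoms ]",
    "; nr type resnr residue atom cgnr charge mass",
    sprintf("  1  OW  1  SOL  OW   1  0.0  %.6f", 15.999),
    sprintf("  2  HW  1  SOL  HW1  1  %s  %.6f", g(params@qH), 1.008),
    sprintf("  3  HW  1  SOL  HW2  1  %s  %.6f", g(params@qH), 1.008),
    sprintf("  4  MW  1  SOL  MW   1  %s  0.0", g(params@qM)),
    "",
    "[ virtual_sites3 ]",
    "; site from1 from2 from3 funct a b   (r = r1 + a r12 + b r13)",
    sprintf("  4  1  2  3  1  %s  %s", g(params@a), g(params@a)),
    "",
    "[ exclusions ]",
    "  1 2 3 4", "  2 1 3 4", "  3 1 2 4", "  4 1 2 3", "")
  if (rigid) {
    dHH <- 2 * params@re * sin(params@thetaE * pi / 360)
    mol <- c(mol,
      "[ settles ]",
      "; O funct dOH(nm) dHH(nm)",
      sprintf("  1  1  %s  %s", g(params@re * dialect$re), g(dHH / 10)),
      "",
      sprintf(";; rwail-extension geometry re_A %s thetae_deg %s",
              g(params@re), g(params@thetaE)))
  } else {
    mol <- c(mol,
      ";; quartic bonds, prefactor convention U = k2/2 d^2 + k3/3 d^3 + k4/4 d^4",
      sprintf(";; rwail-extension quartic-bond re_nm %s k2_kJ_nm2 %s k3_kJ_nm3 %s k4_kJ_nm4 %s",
              g(params@re * dialect$re), g(params@k2 * dialect$k2),
              g(params@k3 * dialect$k3), g(params@k4 * dialect$k4)),
      "",
      "[ angles ]",
      "; i j k funct theta0(deg) k(kJ/mol/rad^2)   U = k/2 (th-th0)^2",
      sprintf("  2  1  3  1  %s  %s", g(params@thetaE),
              g(params@kTheta * dialect$kTheta)))
  }
  writeLines(mol, molPath)
  writeLines(c(
    sprintf("#include \"%s\"", basename(ffPath)),
    sprintf("#include \"%s\"", basename(molPath)),
    "",
    "[ system ]",
    sprintf("rWAIL %s water", params@variant),
    "",
    "[ molecules ]",
    "; compound  nmols",
    "  SOL       1"), topPath)
  invisible(c(topPath, ffPath, molPath))
}

#' Read a Gromacs-dialect topology set
#'
#' Parses the \code{.top} written by \code{\link{writeGromacsTopology}}
#' (following its \code{#include} lines) and reconstructs the
#' \code{ForceFieldParameters} in internal units.  The reader tolerates
#' both the Buckingham atom-type route and a tabulated route in which the
#' nonbonded parameters are carried on an
#' \code{;; rwail-extension buckingham} comment line.
#'
#' @param topPath path to the \code{.top} file
#' @return a \code{ForceFieldParameters}
#' @export
readGromacsTopology <- function(topPath) {
  dir <- dirname(topPath)
  lines <- readLines(topPath)
  inc <- sub('#include\\s+"(.*)"', "\\1", grep("^#include", lines,
                                               value = TRUE))
  for (f in inc) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("missing include '", f, "' next to ", topPath)
    lines <- c(lines, readLines(fp))
  }
  num <- function(x, what, lineNo = NA) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)))
      stop("unparseable ", what, if (!is.na(lineNo)) paste0(" at line ",
                                                            lineNo), ": '",
           x[is.na(v)][1], "'")
    v
  }
  stripped <- sub(";;.*rwail-extension", "EXT", lines)
  section <- ""
  atomtypes <- list()
  vsA <- NA_real_
  settles <- NULL
  angles <- NULL
  ext <- list()
  variant <- sub(".*rWAIL (\\S+) .*", "\\1",
                 grep("^; rWAIL \\S+ (force-field|water)", lines,
                      value = TRUE)[1])
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*;;\\s*rwail-extension", ln)) {
      toks <- strsplit(trimws(sub(".*rwail-extension", "", ln)), "\\s+")[[1]]
      key <- toks[1]
      kv <- toks[-1]
      vals <- as.list(num(kv[seq(2, length(kv), 2)], "extension value", i))
      names(vals) <- kv[seq(1, length(kv), 2)]
      ext[[key]] <- vals
      next
    }
    ln <- sub(";.*", "", ln)
    if (grepl("^\\s*\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (section == "atomtypes" && length(toks) >= 7)
      ## name mass charge ptype A B C6 -> keep the numeric columns
      atomtypes[[toks[1]]] <- num(toks[c(2, 3, 5, 6, 7)],
                                  "atomtype field", i)
    if (section == "virtual_sites3" && length(toks) >= 7)
      vsA <- num(toks[6], "virtual-site coefficient", i)
    if (section == "settles" && length(toks) >= 4)
      settles <- num(toks[3:4], "settles distance", i)
    if (section == "angles" && length(toks) >= 6)
      angles <- num(toks[5:6], "angle parameter", i)
  }
  if (is.null(atomtypes$OW)) stop("no OW atom type found")
  ow <- atomtypes$OW                    # mass charge A B C6
  if (all(ow[3:5] == 0) && !is.null(ext$buckingham)) {
    b <- ext$buckingham
    AOO <- fromDialect(b$A_kJ, dialect$A)
    alpha <- fromDialect(b$B_nm, dialect$B)
    COO <- fromDialect(b$C6_kJ_nm6, dialect$C6)
  } else {
    AOO <- fromDialect(ow[3], dialect$A)
    alpha <- fromDialect(ow[4], dialect$B)
    COO <- fromDialect(ow[5], dialect$C6)
  }
  qH <- atomtypes$HW[2]
  qM <- atomtypes$MW[2]
  if (is.null(ext$`hb-wall`)) stop("missing hb-wall extension block")
  A4 <- fromDialect(ext$`hb-wall`$A4_kJ_nm4, dialect$A4)
  rc <- fromDialect(ext$`hb-wall`$rc_nm, dialect$rc)
  if (!is.null(settles)) {
    re <- fromDialect(settles[1], dialect$re)
    thetaE <- if (!is.null(ext$geometry)) ext$geometry$thetae_deg
      else 2 * asin(settles[2] / (2 * settles[1])) * 180 / pi
    k2 <- k3 <- k4 <- kTheta <- NA_real_
  } else {
    qb <- ext$`quartic-bond`
    if (is.null(qb) || is.null(angles))
      stop("flexible topology requires quartic-bond extension and angles")
    re <- fromDialect(qb$re_nm, dialect$re)
    k2 <- fromDialect(qb$k2_kJ_nm2, dialect$k2)
    k3 <- fromDialect(qb$k3_kJ_nm3, dialect$k3)
    k4 <- fromDialect(qb$k4_kJ_nm4, dialect$k4)
    thetaE <- angles[1]
    kTheta <- fromDialect(angles[2], dialect$kTheta)
  }
  new("ForceFieldParameters", variant = variant, qM = qM, qH = qH,
      a = vsA, AOO = AOO, alpha = alpha, COO = COO, A4 = A4, rc = rc,
      re = re, thetaE = thetaE, k2 = k2, k3 = k3, k4 = k4, kTheta = kTheta)
}

## --------------------------------------------------------------------------

#' Write / read a time-series CSV
#'
#' Plain CSV with a \code{time} column (ps) and one column per observable;
#' the documented interchange format between the engine and the estimators.
#'
#' @param series data.frame (e.g. \code{trajectorySeries(traj)})
#' @param path file path
#' @return \code{path} (writer) / data.frame (reader)
#' @export
writeTimeSeriesCsv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeriesCsv
#' @export
readTimeSeriesCsv <- function(path) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df))
    stop("time-series CSV must carry a 'time' column")
  df
}

#' Read and validate a run configuration
#'
#' Structured-text (YAML) configuration mirroring the simulation-protocol
#' vocabulary: \code{integrator}, \code{dt}, \code{steps}, \code{tau_t},
#' \code{tau_p}, \code{T}, \code{P}, \code{r_cut}, \code{lrc_energy},
#' \code{lrc_pressure}, \code{variant}, \code{seed}.
#'
#' @param path YAML file
#' @return validated named list
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("integrator", "dt", "steps", "tau_t", "tau_p", "T", "P",
             "r_cut", "lrc_energy", "lrc_pressure", "variant", "seed",
             "n_molecules", "density", "sample_every", "snapshot_every",
             "ewald_tol")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("invalid configuration keys: ", paste(bad, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "))
  if (!is.null(cfg$integrator) &&
      !cfg$integrator %in% c("nve", "nvt", "npt"))
    stop("invalid configuration: integrator must be nve, nvt or npt")
  cfg
}
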