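# Sequence threading onto fixed backbones with deterministic greedy
# side-chain repacking and a soft-steric per-chain score, feeding the
# all-vs-all specificity matrix normalised to each sequence's cognate
# structure.

#' Soft-steric scoring parameters
#'
#' The steric score sums, over all inter-chain heavy-atom pairs closer
#' than s(ri+rj), the penalty k((s(ri+rj)-d)/(s(ri+rj)))^2, shared half
#' and half between the two chains. The total score additionally rewards
#' each inter-chain apolar (C/S) pair in the shell [s(ri+rj),
#' s(ri+rj)+shell] with -c points (a minimal burial surrogate). Score
#' values are reported in arbitrary "points"; only relative,
#' cognate-normalized comparisons are meaningful.
#'
#' @param s softness: fraction of the vdW contact distance where the
#'   penalty sets in (default 0.90)
#' @param k penalty scale in points (default 100)
#' @param c contact reward in points (default 1)
#' @param shell reward shell width in Angstroms (default 1.5)
#' @return list of class \code{"StericParams"}
#' @export
stericParams <- function(s = 0.90, k = 100, c = 1, shell = 1.5) {
  if (s <= 0 || s > 1) stop("softness s must be in (0, 1]")
  if (k <= 0) stop("penalty scale k must be positive")
  p <- list(s = s, k = k, c = c, shell = shell)
  class(p) <- "StericParams"
  p
}

.ROTAMER_CHI <- c(-60, 60, 180)

#' Backbone-independent rotamer library
#'
#' All combinations of chi angles in \{-60, 60, 180\} for the residue's
#' rotatable side-chain bonds (at most 81 rotamers). Residues with no
#' rotatable chi (Gly, Ala, Pro) have a single fixed conformation.
#'
#' @param resname 3-letter residue code
#' @return numeric matrix, one row per rotamer, one column per chi angle
#' @export
rotamerLibrary <- function(resname) {
  nchi <- .N_CHI[[resname]]
  if (is.null(nchi) || nchi == 0)
    return(matrix(numeric(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(.ROTAMER_CHI), nchi)))
}

# Rotamer side-chain coordinates (atoms beyond CB) cached in a local
# backbone frame (origin CA; e1 = CA->CB, e2 = component of CA->N
# perpendicular to e1, e3 = e1 x e2). Ideal internal geometry makes these
# identical for every residue of a type, so repacking only transforms them.
.rotamerCache <- new.env(parent = emptyenv())

.residueFrame <- function(N, CA, CB) {
  e1 <- unitVec(CB - CA)
  v <- N - CA
  e2 <- unitVec(v - sum(v * e1) * e1)
  cbind(e1, e2, crossProd3(e1, e2))
}

.rotamerCoordsLocal <- function(resname) {
  hit <- .rotamerCache[[resname]]
  if (!is.null(hit)) return(hit)
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- nerfPlace(c(0, -1, 0), N, CA, 1.525, 111.2, -120)
  CB <- placeCB(N, CA, C)
  B <- .residueFrame(N, CA, CB)
  lib <- rotamerLibrary(resname)
  out <- lapply(seq_len(nrow(lib)), function(r) {
    sc <- buildSideChain(resname, N, CA, CB, lib[r, ])
    if (is.null(sc)) return(NULL)
    sweep(sc, 2, CA) %*% B   # local coordinates, rownames = atom names
  })
  .rotamerCache[[resname]] <- out
  out
}

# Condition used to flag sequence/structure chain-length mismatches.
.lengthMismatch <- function(msg) {
  structure(class = c("ccbarrelLengthMismatch", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Thread a sequence onto a fixed backbone
#'
#' Replaces every residue's side chain by the target residue type at
#' idealized geometry in the default (extended, all-chi-180) rotamer,
#' leaving backbone N, CA, C, O untouched; CB is rebuilt from the
#' backbone. The same sequence is applied to every chain (homomeric
#' threading). SCC pseudoatoms are dropped. A chain whose residue count
#' differs from the sequence length raises a length-mismatch condition
#' that \code{\link{specificityMatrix}} converts into a missing cell.
#'
#' @param structure a \linkS4class{StructureModel} with backbone N, CA, C
#' @param sequence amino-acid string, one letter per residue of each chain
#' @return a \linkS4class{StructureModel} with rebuilt side chains
#' @export
mutateOntoBackbone <- function(structure, sequence) {
  stopifnot(is(structure, "StructureModel"))
  seq1 <- strsplit(sequence, "")[[1]]
  if (!all(seq1 %in% names(.AA3))) stop("unknown amino-acid code in sequence")
  targets <- .AA3[seq1]
  a <- structure@atoms[structure@atoms$elety != "SCC", , drop = FALSE]
  pieces <- list()
  for (ch in unique(a$chain)) {
    achn <- a[a$chain == ch, , drop = FALSE]
    resnos <- unique(achn$resno)
    if (length(resnos) != length(targets))
      stop(.lengthMismatch(sprintf(
        "chain %s has %d residues; sequence has %d", ch, length(resnos),
        length(targets))))
    for (ri in seq_along(resnos)) {
      res <- achn[achn$resno == resnos[ri], , drop = FALSE]
      bb <- res[res$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
      if (!all(c("N", "CA", "C") %in% bb$elety))
        stop("residue ", ch, ":", resnos[ri], " missing backbone atoms")
      getPos <- function(nm) as.numeric(bb[bb$elety == nm, c("x", "y", "z")][1, ])
      rn <- targets[[ri]]
      bb$resname <- rn
      out <- bb
      if (rn != "GLY") {
        cb <- placeCB(getPos("N"), getPos("CA"), getPos("C"))
        sc <- buildSideChain(rn, getPos("N"), getPos("CA"), cb)
        extra <- rbind(CB = cb, sc)
        add <- bb[rep(1, nrow(extra)), , drop = FALSE]
        add$elety <- rownames(extra)
        add$elesy <- atomElement(rownames(extra))
        add$x <- extra[, 1]; add$y <- extra[, 2]; add$z <- extra[, 3]
        out <- rbind(bb, add)
      }
      pieces[[length(pieces) + 1]] <- out
    }
  }
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  initialize(structure, atoms = atoms,
             source = paste0(structure@source, "+threaded"))
}

# Soft-steric pair penalty between two coordinate sets with radii.
.softPenalty <- function(A, rA, B, rB, params) {
  if (nrow(A) == 0 || nrow(B) == 0) return(0)
  d <- sqrt(crossDist2(A, B))
  lim <- params$s * outer(rA, rB, "+")
  over <- d < lim
  if (!any(over)) return(0)
  frac <- (lim[over] - d[over]) / lim[over]
  params$k * sum(frac^2)
}

#' Greedy deterministic side-chain repacking
#'
#' Iterative sweeps in fixed residue order (chain, then residue number):
#' each residue adopts the library rotamer minimising the soft-steric
#' interaction of its movable side-chain atoms (beyond CB) with all atoms
#' of other residues, keeping its current rotamer on ties. Terminates when
#' a sweep changes nothing or after \code{maxSweeps}. Fully deterministic;
#' repacking an already-converged model is a no-op.
#'
#' @param model a threaded \linkS4class{StructureModel}
#' @param maxSweeps sweep cap (default 10)
#' @param params \code{\link{stericParams}}
#' @param contextRadius neighbourhood radius (A) around each CA within
#'   which context atoms are collected (default 14)
#' @return the repacked \linkS4class{StructureModel}
#' @export
repack <- function(model, maxSweeps = 10, params = stericParams(),
                   contextRadius = 14) {
  a <- model@atoms
  key <- paste(a$chain, a$resno, sep = ":")
  ukeys <- unique(key)
  resRows <- split(seq_len(nrow(a)), factor(key, levels = ukeys))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- vdwRadius(a$elesy)
  elety <- a$elety
  resname <- vapply(resRows, function(r) a$resname[r[1]], character(1))
  # movable atoms (beyond CB), rotamer candidate coordinates per residue
  # (backbones are fixed, so frames and candidates are computed once)
  movable <- lapply(resRows, function(r)
    r[!(elety[r] %in% c("N", "CA", "C", "O", "CB"))])
  candidates <- vector("list", length(ukeys))
  caIdx <- vapply(resRows, function(r) r[elety[r] == "CA"][1], integer(1))
  for (i in seq_along(ukeys)) {
    mv <- movable[[i]]
    if (length(mv) == 0) next
    lib <- rotamerLibrary(resname[i])
    if (ncol(lib) == 0) next
    rows <- resRows[[i]]
    anchor <- function(nm) xyz[rows[elety[rows] == nm][1], ]
    B <- .residueFrame(anchor("N"), anchor("CA"), anchor("CB"))
    caPos <- anchor("CA")
    local <- .rotamerCoordsLocal(resname[i])
    mvNames <- elety[mv]
    candidates[[i]] <- lapply(local, function(lc)
      sweep(lc[mvNames, , drop = FALSE] %*% t(B), 2, -caPos))
  }
  for (sweep in seq_len(maxSweeps)) {
    changed <- FALSE
    for (i in seq_along(ukeys)) {
      cands <- candidates[[i]]
      if (is.null(cands)) next
      rows <- resRows[[i]]
      mv <- movable[[i]]
      caPos <- xyz[caIdx[i], ]
      # context: atoms of other residues near this CA
      near <- which(sqrt(rowSums(sweep(xyz, 2, caPos)^2)) <= contextRadius)
      ctx <- setdiff(near, rows)
      ctxXyz <- xyz[ctx, , drop = FALSE]
      ctxR <- radii[ctx]
      mvR <- radii[mv]
      cur <- .softPenalty(xyz[mv, , drop = FALSE], mvR, ctxXyz, ctxR, params)
      bestE <- cur
      bestXyz <- NULL
      for (r in seq_along(cands)) {
        e <- .softPenalty(cands[[r]], mvR, ctxXyz, ctxR, params)
        if (e < bestE - 1e-9) {
          bestE <- e
          bestXyz <- cands[[r]]
        }
      }
      if (!is.null(bestXyz)) {
        xyz[mv, ] <- bestXyz
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  initialize(model, atoms = a)
}

# Shared machinery for per-chain scores.
.interChainPairs <- function(model) {
  a <- model@atoms[model@atoms$elety != "SCC", , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       chain = a$chain, radii = vdwRadius(a$elesy),
       apolar = a$elesy %in% c("C", "S"),
       chains = unique(a$chain))
}

#' Per-chain soft-steric clash score
#'
#' Sums the soft penalty over all inter-chain heavy-atom pairs (intra-chain
#' pairs are ignored), each pair contributing half to each chain.
#'
#' @param model a \linkS4class{StructureModel} with >= 2 chains
#' @param params \code{\link{stericParams}}
#' @return named numeric vector of per-chain scores (points)
#' @export
stericScore <- function(model, params = stericParams()) {
  .chainScores(model, params, reward = FALSE)
}

#' Per-chain total score (steric plus contact reward)
#'
#' The steric clash score minus \code{c} points for every inter-chain
#' apolar (C or S) heavy-atom pair within the reward shell; equals
#' \code{\link{stericScore}} when \code{c = 0}.
#'
#' @inheritParams stericScore
#' @return named numeric vector of per-chain scores (points)
#' @export
totalScore <- function(model, params = stericParams()) {
  .chainScores(model, params, reward = TRUE)
}

.chainScores <- function(model, params, reward) {
  pp <- .interChainPairs(model)
  if (length(pp$chains) < 2) stop("need at least 2 chains to score")
  out <- structure(numeric(length(pp$chains)), names = pp$chains)
  ch <- pp$chains
  for (i in seq_along(ch)) for (j in seq_along(ch)) {
    if (j <= i) next
    selI <- pp$chain == ch[i]
    selJ <- pp$chain == ch[j]
    d <- sqrt(crossDist2(pp$xyz[selI, , drop = FALSE],
                         pp$xyz[selJ, , drop = FALSE]))
    lim <- params$s * outer(pp$radii[selI], pp$radii[selJ], "+")
    over <- d < lim
    pen <- 0
    if (any(over))
      pen <- params$k * sum(((lim[over] - d[over]) / lim[over])^2)
    val <- pen
    if (reward && params$c != 0) {
      ap <- outer(pp$apolar[selI], pp$apolar[selJ], "&")
      inShell <- ap & d >= lim & d <= lim + params$shell
      val <- val - params$c * sum(inShell)
    }
    out[i] <- out[i] + val / 2
    out[j] <- out[j] + val / 2
  }
  out
}

#' All-vs-all threading specificity matrix
#'
#' Threads every sequence onto every structure, repacks side chains,
#' scores each model per chain, and normalises each row by subtracting
#' the sequence's score on its declared cognate structure: cognate cells
#' are exactly zero, positive cells mean the sequence fits that structure
#' worse than its own, negative cells better. Sequence/structure pairs
#' with incompatible chain lengths become missing cells.
#'
#' @param sequences named character vector of amino-acid strings
#' @param structures named list of \linkS4class{StructureModel}
#' @param cognate named character vector mapping each sequence name to a
#'   structure name
#' @param score \code{"steric"} or \code{"total"}
#' @param params \code{\link{stericParams}}
#' @param maxSweeps repacking sweep cap
#' @return a \linkS4class{SpecificityMatrix}
#' @export
specificityMatrix <- function(sequences, structures, cognate,
                              score = c("steric", "total"),
                              params = stericParams(), maxSweeps = 10) {
  score <- match.arg(score)
  if (is.null(names(sequences)) || is.null(names(structures)))
    stop("sequences and structures must be named")
  if (!all(names(sequences) %in% names(cognate)))
    stop("every sequence needs a declared cognate structure")
  if (!all(cognate[names(sequences)] %in% names(structures)))
    stop("cognate structures missing from the structure set")
  nS <- length(sequences); nT <- length(structures)
  raw <- matrix(NA_real_, nS, nT,
                dimnames = list(names(sequences), names(structures)))
  sdm <- raw
  scorer <- if (score == "steric") stericScore else totalScore
  for (si in names(sequences)) for (ti in names(structures)) {
    model <- tryCatch(mutateOntoBackbone(structures[[ti]], sequences[[si]]),
                      ccbarrelLengthMismatch = function(e) NULL)
    if (is.null(model)) next
    model <- repack(model, maxSweeps = maxSweeps, params = params)
    perChain <- scorer(model, params)
    raw[si, ti] <- mean(perChain)
    sdm[si, ti] <- stats::sd(perChain)
  }
  values <- raw
  for (si in names(sequences)) {
    cg <- cognate[[si]]
    if (is.na(raw[si, cg]))
      stop("cognate cell for sequence ", si, " could not be scored")
    values[si, ] <- raw[si, ] - raw[si, cg]
    values[si, cg] <- 0
  }
  new("SpecificityMatrix", values = values, raw = raw, sd = sdm,
      cognate = cognate[names(sequences)], score = score)
}
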