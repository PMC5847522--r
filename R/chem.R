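# Standard average atomic masses (Da) for molecular-weight sums.
ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904
)

parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula) {
    abort(paste0("cannot parse molecular formula: ", formula))
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  ct[is.na(ct)] <- 1L
  setNames(ct, el)
}

#' Molecular weight
#'
#' Sum of standard average atomic masses over all atoms, with implicit
#' hydrogens included.  Accepts a molecule or a molecular formula string
#' (e.g. `"C20H24O2"`).
#'
#' @param mol A `small_mol` or a formula string.
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(mol) {
  if (is.character(mol)) {
    counts <- parse_formula(mol)
    unknown <- setdiff(names(counts), names(ATOMIC_MASS))
    if (length(unknown)) {
      abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
    }
    return(sum(ATOMIC_MASS[names(counts)] * counts))
  }
  el <- mol$atoms$element
  unknown <- setdiff(el, names(ATOMIC_MASS))
  if (length(unknown)) {
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  sum(ATOMIC_MASS[el]) + sum(mol$atoms$h_count) * ATOMIC_MASS[["H"]]
}

# per-atom bond environment used by the TPSA fragment classifier
atom_environment <- function(mol) {
  n <- nrow(mol$atoms)
  ns <- nd <- nt <- nar <- integer(n)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (b$aromatic[k]) {
      nar[i] <- nar[i] + 1L; nar[j] <- nar[j] + 1L
    } else if (b$order[k] == 1) {
      ns[i] <- ns[i] + 1L; ns[j] <- ns[j] + 1L
    } else if (b$order[k] == 2) {
      nd[i] <- nd[i] + 1L; nd[j] <- nd[j] + 1L
    } else if (b$order[k] == 3) {
      nt[i] <- nt[i] + 1L; nt[j] <- nt[j] + 1L
    }
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # 3-membered ring membership: two neighbours that are themselves bonded
  in3 <- logical(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) >= 2) {
      for (p in seq_len(length(nb) - 1)) {
        for (q in (p + 1):length(nb)) {
          if (any((b$i == nb[p] & b$j == nb[q]) | (b$i == nb[q] & b$j == nb[p]))) {
            in3[i] <- TRUE
          }
        }
      }
    }
  }
  list(ns = ns, nd = nd, nt = nt, nar = nar, in3 = in3)
}

tpsa_contribution_O <- function(arom, chg, h, ns, nd, nar, in3) {
  if (arom && nar >= 2) return(13.14)
  if (chg == -1 && ns == 1 && nd == 0) return(23.06)
  if (chg == 0 && h >= 1 && ns >= 1 && nd == 0) return(20.23)
  if (chg == 0 && h == 0 && nd == 1 && ns == 0) return(17.07)
  if (chg == 0 && h == 0 && ns == 2 && in3) return(12.53)
  if (chg == 0 && h == 0 && ns == 2) return(9.23)
  NA_real_
}

tpsa_contribution_N <- function(arom, chg, h, ns, nd, nt, nar, in3) {
  if (arom) {
    if (chg == 0) {
      if (h == 0 && nar == 2 && ns == 0 && nd == 0) return(12.89)
      if (h == 0 && nar == 3) return(4.41)
      if (h == 0 && nar == 2 && ns == 1) return(4.93)
      if (h == 0 && nar == 2 && nd == 1) return(8.39)
      if (h == 1 && nar == 2) return(15.79)
    } else if (chg == 1) {
      if (h == 0 && nar == 3) return(4.10)
      if (h == 0 && nar == 2 && ns == 1) return(3.88)
      if (h == 1 && nar == 2) return(14.14)
    }
    return(NA_real_)
  }
  if (chg == 0) {
    if (h == 0 && ns == 3 && in3) return(3.01)
    if (h == 0 && ns == 3) return(3.24)
    if (h == 0 && ns == 1 && nd == 1) return(12.36)
    if (h == 0 && nt == 1 && ns == 0) return(23.79)
    if (h == 0 && ns == 1 && nd == 2) return(11.68)
    if (h == 0 && nd == 1 && nt == 1) return(13.60)
    if (h == 1 && ns == 2 && in3) return(21.94)
    if (h == 1 && ns == 2) return(12.03)
    if (h == 1 && nd == 1 && ns == 0) return(23.85)
    if (h == 2 && ns == 1) return(26.02)
  } else if (chg == 1) {
    if (h == 0 && ns == 4) return(0.00)
    if (h == 0 && ns == 2 && nd == 1) return(3.01)
    if (h == 0 && ns == 1 && nt == 1) return(4.36)
    if (h == 1 && ns == 3) return(4.44)
    if (h == 1 && ns == 1 && nd == 1) return(13.97)
    if (h == 2 && ns == 2) return(16.61)
    if (h == 2 && nd == 1 && ns == 0) return(25.59)
    if (h == 3 && ns == 1) return(27.64)
  }
  NA_real_
}

tpsa_contribution_S <- function(arom, chg, h, ns, nd, nar) {
  if (arom) {
    if (nar == 2 && nd == 0) return(28.24)
    if (nar == 2 && nd == 1) return(21.70)
    return(NA_real_)
  }
  if (h == 1 && ns == 1) return(38.80)
  if (h == 0 && ns == 2 && nd == 0) return(25.30)
  if (h == 0 && nd == 1 && ns == 0) return(32.09)
  if (h == 0 && ns == 2 && nd == 1) return(19.21)
  if (h == 0 && ns == 2 && nd == 2) return(8.38)
  NA_real_
}

tpsa_contribution_P <- function(h, ns, nd) {
  if (h == 0 && ns == 3 && nd == 0) return(13.59)
  if (h == 0 && ns == 1 && nd == 1) return(34.14)
  if (h == 0 && ns == 3 && nd == 1) return(9.81)
  if (h == 1 && ns == 2 && nd == 1) return(23.47)
  NA_real_
}

#' Topological polar surface area (Ertl)
#'
#' Fragment-additive TPSA: each N and O atom contributes a tabulated surface
#' increment determined by its bonding environment (hybridization, attached
#' hydrogens, charge, ring membership).  Sulfur and phosphorus contributions
#' are off by default (the N/O convention).  An atom environment missing from
#' the table contributes zero with a warning.
#'
#' @param mol A `small_mol`.
#' @param include_sp Include S and P contributions (default `FALSE`).
#' @return TPSA in squared Angstrom.
#' @export
tpsa <- function(mol, include_sp = FALSE) {
  env <- atom_environment(mol)
  a <- mol$atoms
  total <- 0
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    contrib <- switch(el,
      O = tpsa_contribution_O(a$aromatic[i], a$charge[i], a$h_count[i],
        env$ns[i], env$nd[i], env$nar[i], env$in3[i]),
      N = tpsa_contribution_N(a$aromatic[i], a$charge[i], a$h_count[i],
        env$ns[i], env$nd[i], env$nt[i], env$nar[i], env$in3[i]),
      S = if (include_sp) {
        tpsa_contribution_S(a$aromatic[i], a$charge[i], a$h_count[i],
          env$ns[i], env$nd[i], env$nar[i])
      } else {
        0
      },
      P = if (include_sp) {
        tpsa_contribution_P(a$h_count[i], env$ns[i], env$nd[i])
      } else {
        0
      },
      0
    )
    if (is.na(contrib)) {
      warn(sprintf(
        "no TPSA fragment for %s atom %d (environment not in table); contributing 0",
        el, i
      ))
      contrib <- 0
    }
    total <- total + contrib
  }
  total
}

mol_to_sdfset <- function(mol) {
  txt <- mol_to_sdf(mol)
  if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$")
  sdfstr <- ChemmineR::read.SDFstr(textConnection(strsplit(txt, "\n")[[1]]))
  methods::as(sdfstr, "SDFset")
}

#' Crippen logP
#'
#' Octanol-water partition coefficient as the sum of Wildman-Crippen atomic
#' contributions (computed by OpenBabel's implementation of the scheme).
#'
#' @param mol A `small_mol`.
#' @return logP (unitless).
#' @export
clogp <- function(mol) {
  props <- ChemmineR::propOB(mol_to_sdfset(mol))
  as.numeric(props$logP[1])
}

#' Path fingerprint of a molecule
#'
#' OpenBabel FP2: hashed linear paths of length 1-7 folded into 1024 bits.
#'
#' @param mol A `small_mol`.
#' @return An object of class `chem_fp` (1024 logical bits plus scheme id).
#' @export
fingerprint <- function(mol) {
  fp <- ChemmineR::fingerprintOB(mol_to_sdfset(mol), "FP2")
  bits <- as.logical(as.numeric(ChemmineR::as.matrix(fp)[1, ]))
  structure(list(bits = bits, scheme = "FP2"), class = "chem_fp")
}

#' Tanimoto coefficient of two fingerprints
#'
#' Bit-set intersection over union; identical molecules score 1 (including
#' the degenerate case of two empty bit sets).
#'
#' @param a,b `chem_fp` objects of the same scheme.
#' @return TC in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (!identical(a$scheme, b$scheme)) abort("fingerprint schemes differ")
  u <- sum(a$bits | b$bits)
  if (u == 0) return(if (identical(a$bits, b$bits)) 1 else 0)
  sum(a$bits & b$bits) / u
}

# adjacency list with bond attributes for the MCS search
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    adj[[i]] <- rbind(adj[[i]], c(j, b$order[k], b$aromatic[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, b$order[k], b$aromatic[k]))
  }
  adj
}

mol_connected <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1) return(TRUE)
  adj <- mol_adjacency(mol)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (u in nb[, 1]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
  }
  all(seen)
}

#' Maximum common connected substructure
#'
#' Exact branch-and-bound search for the largest connected common subgraph of
#' two molecules, with atoms matched on (element, aromatic flag).  By default
#' bond-order mismatches between aromatic forms are tolerated (any bond
#' matches any bond); `strict_bonds = TRUE` additionally requires equal order
#' or joint aromaticity.  When the time budget is exhausted the best mapping
#' found so far is returned with `exact = FALSE` (a lower bound).
#'
#' @param a,b Connected `small_mol` objects.
#' @param timeout Time budget in seconds (default 10).
#' @param strict_bonds Require matching bond orders (default `FALSE`).
#' @return List with `count`, `mapping` (tibble `a_atom`, `b_atom`) and
#'   `exact` flag.
#' @export
mcs_common_atoms <- function(a, b, timeout = 10, strict_bonds = FALSE) {
  if (nrow(a$atoms) == 0 || nrow(b$atoms) == 0) abort("empty molecule")
  if (!mol_connected(a) || !mol_connected(b)) {
    abort("both molecular graphs must be connected")
  }
  na <- nrow(a$atoms)
  nb <- nrow(b$atoms)
  adj_a <- mol_adjacency(a)
  adj_b <- mol_adjacency(b)
  atom_ok <- function(i, j) {
    a$atoms$element[i] == b$atoms$element[j] &&
      a$atoms$aromatic[i] == b$atoms$aromatic[j]
  }
  bond_ok <- function(ea, eb) {
    if (!strict_bonds) return(TRUE)
    (ea[3] == 1 && eb[3] == 1) || (ea[3] == 0 && eb[3] == 0 && ea[2] == eb[2])
  }
  deadline <- proc.time()[["elapsed"]] + timeout
  best <- list(count = 0L, map_a = integer(), map_b = integer())
  exact <- TRUE
  seen_states <- new.env(hash = TRUE, parent = emptyenv())
  extend <- function(map_a, map_b) {
    if (proc.time()[["elapsed"]] > deadline) {
      exact <<- FALSE
      return()
    }
    # the same pair set is reachable in many orders; expand each set once
    key <- paste(sort(paste0(map_a, ":", map_b)), collapse = "|")
    if (!is.null(seen_states[[key]])) return()
    seen_states[[key]] <- TRUE
    k <- length(map_a)
    if (k > best$count) {
      best <<- list(count = k, map_a = map_a, map_b = map_b)
    }
    if (k + min(na - k, nb - k) <= best$count) return()
    # frontier: unmapped atom pairs adjacent to corresponding mapped atoms
    cand <- NULL
    for (m in seq_len(k)) {
      ia <- map_a[m]
      ib <- map_b[m]
      nb_a <- adj_a[[ia]]
      nb_b <- adj_b[[ib]]
      if (is.null(nb_a) || is.null(nb_b)) next
      for (p in seq_len(nrow(nb_a))) {
        u <- nb_a[p, 1]
        if (u %in% map_a) next
        for (q in seq_len(nrow(nb_b))) {
          v <- nb_b[q, 1]
          if (v %in% map_b) next
          if (atom_ok(u, v) && bond_ok(nb_a[p, ], nb_b[q, ])) {
            cand <- rbind(cand, c(u, v))
          }
        }
      }
    }
    if (is.null(cand)) return()
    cand <- unique(cand)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    tried <- NULL
    for (r in seq_len(nrow(cand))) {
      u <- cand[r, 1]
      v <- cand[r, 2]
      extend(c(map_a, u), c(map_b, v))
    }
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (atom_ok(i, j)) extend(i, j)
      if (proc.time()[["elapsed"]] > deadline) break
    }
  }
  list(
    count = best$count,
    mapping = tibble(a_atom = best$map_a, b_atom = best$map_b),
    exact = exact
  )
}

#' Descriptor set of a molecule
#'
#' @param mol A `small_mol`.
#' @return One-row tibble with `mw` (Da), `logp`, `tpsa` (squared Angstrom).
#' @export
descriptor_set <- function(mol) {
  tibble(id = mol$id, mw = molecular_weight(mol), logp = clogp(mol),
    tpsa = tpsa(mol))
}
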