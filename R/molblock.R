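#' @title V2000 molblock graph layer
#' @description Internal fixed-width readers/writers for the V2000
#'   connection table, plus the valence model used to sanitize mutants.
#'   Graphs are plain lists: `atoms` (data.frame: elem, charge, parity) and
#'   `bonds` (data.frame: a1, a2, order, stereo). Coordinates are always 0
#'   (0D); tetrahedral stereo rides on atom parity and double-bond geometry
#'   on directional bond-stereo codes, both of which OpenBabel honours for
#'   0D structures. Isotope annotations (`M  ISO`) are dropped on parse:
#'   single-atom modification analysis concerns heavy-atom identity only.
#' @name molblock
#' @keywords internal
NULL

# Allowed valences (sum of kekulized bond orders) by element and formal
# charge. Elements/charges not listed are not valence-checked.
.VALENCES <- list(
  "C|0" = 4L, "C|1" = 3L, "C|-1" = 3L,
  "N|0" = 3L, "N|1" = 4L, "N|-1" = 2L,
  "O|0" = 2L, "O|1" = 3L, "O|-1" = 1L,
  "S|0" = c(2L, 4L, 6L), "S|1" = c(3L, 5L), "S|-1" = 1L,
  "P|0" = c(3L, 5L), "P|1" = 4L,
  "F|0" = 1L, "Cl|0" = 1L, "Br|0" = 1L, "I|0" = 1L,
  "F|-1" = 0L, "Cl|-1" = 0L, "Br|-1" = 0L, "I|-1" = 0L,
  "B|0" = 3L, "Si|0" = 4L, "Se|0" = c(2L, 4L, 6L), "As|0" = c(3L, 5L)
)

allowed_valences <- function(elem, charge) {
  .VALENCES[[paste0(elem, "|", charge)]]
}

# Sum of bond orders incident to each atom.
bond_order_sums <- function(graph) {
  n <- nrow(graph$atoms)
  s <- integer(n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      b <- graph$bonds[k, ]
      s[b$a1] <- s[b$a1] + b$order
      s[b$a2] <- s[b$a2] + b$order
    }
  }
  s
}

# TRUE when every (known) atom admits an allowed valence >= its bond-order
# sum. Unknown element/charge combinations are not checked.
valence_ok <- function(graph) {
  sums <- bond_order_sums(graph)
  for (i in seq_len(nrow(graph$atoms))) {
    v <- allowed_valences(graph$atoms$elem[i], graph$atoms$charge[i])
    if (is.null(v)) next
    if (!any(v >= sums[i])) return(FALSE)
  }
  TRUE
}

# TRUE when element `elem` (neutral) could sit at atom `i` of `graph`.
site_accepts <- function(graph, i, elem, sums = NULL) {
  if (is.null(sums)) sums <- bond_order_sums(graph)
  v <- allowed_valences(elem, 0L)
  !is.null(v) && any(v >= sums[i])
}

parse_molblock <- function(lines) {
  if (length(lines) < 4L) return(NULL)
  counts <- lines[[4L]]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds)) return(NULL)
  if (length(lines) < 4L + natoms + nbonds) return(NULL)
  at <- lines[seq_len(natoms) + 4L]
  atoms <- data.frame(
    elem = trimws(substr(at, 32L, 34L)),
    charge = 0L,
    parity = {
      p <- suppressWarnings(as.integer(substr(at, 40L, 42L)))
      ifelse(is.na(p), 0L, p)
    },
    stringsAsFactors = FALSE
  )
  bonds <- if (nbonds) {
    bl <- lines[seq_len(nbonds) + 4L + natoms]
    data.frame(
      a1 = as.integer(substr(bl, 1L, 3L)),
      a2 = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L)),
      stereo = {
        s <- suppressWarnings(as.integer(substr(bl, 10L, 12L)))
        ifelse(is.na(s), 0L, s)
      }
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0),
               order = integer(0), stereo = integer(0))
  }
  # property block: apply M CHG, drop M ISO (isotopes cleared by design)
  rest <- lines[-seq_len(4L + natoms + nbonds)]
  for (ln in rest) {
    if (startsWith(ln, "M  CHG")) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))),
                                                "\\s+")[[1L]]))
      if (length(f) >= 3L) {
        k <- f[[1L]]
        for (j in seq_len(k)) {
          idx <- f[2L * j]; chg <- f[2L * j + 1L]
          if (!is.na(idx) && idx >= 1L && idx <= natoms) atoms$charge[idx] <- chg
        }
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Render a graph as a V2000 molblock; `title` becomes the record name used
# to map batch output back to inputs.
write_molblock <- function(graph, title = "") {
  atoms <- graph$atoms
  bonds <- graph$bonds
  # chiral flag set whenever any parity is present
  chiral <- as.integer(any(atoms$parity %in% c(1L, 2L)))
  out <- c(
    title, " samcliff", "",
    sprintf("%3d%3d  0  0%3d  0  0  0  0  0999 V2000",
            nrow(atoms), nrow(bonds), chiral),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0%3d  0  0  0  0  0  0  0  0  0",
            atoms$elem, atoms$parity)
  )
  if (nrow(bonds)) {
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0",
                          bonds$a1, bonds$a2, bonds$order, bonds$stereo))
  }
  chg <- which(atoms$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8L))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, atoms$charge[grp]),
                                  collapse = "")))
    }
  }
  c(out, "M  END", "$$$$")
}

# Connected components over the bond graph; returns integer component id
# per atom.
graph_components <- function(graph) {
  n <- nrow(graph$atoms)
  comp <- integer(n)
  if (!n) return(comp)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a1[k]; b <- graph$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!comp[w]) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# Extract the induced subgraph on `keep` (a logical or integer index).
# Relative atom order is preserved, so atom parities remain valid.
subgraph <- function(graph, keep) {
  idx <- if (is.logical(keep)) which(keep) else sort(keep)
  map <- integer(nrow(graph$atoms))
  map[idx] <- seq_along(idx)
  bsel <- graph$bonds$a1 %in% idx & graph$bonds$a2 %in% idx
  bonds <- graph$bonds[bsel, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]
  bonds$a2 <- map[bonds$a2]
  rownames(bonds) <- NULL
  atoms <- graph$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  list(atoms = atoms, bonds = bonds)
}

# Number of inversions of an integer sequence (parity of the permutation
# needed to sort it).
.inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  inv <- 0L
  for (i in seq_len(n - 1L)) inv <- inv + sum(x[(i + 1L):n] < x[i])
  inv
}

#' Renumber the atoms of a molecular graph
#'
#' Reorders atoms according to `perm` (`perm[i]` is the new index of old
#' atom `i`) and rewrites bonds accordingly. Tetrahedral atom parities are
#' flipped when the renumbering changes the neighbour order by an odd
#' permutation (MDL parity is defined relative to ascending atom numbers;
#' an implicit hydrogen always ranks last and is unaffected by heavy-atom
#' renumbering). Used to prove that canonical keys are invariant to input
#' atom ordering.
#'
#' @param graph internal graph (atoms/bonds list).
#' @param perm integer permutation of `seq_len(n_atoms)`.
#' @return the renumbered graph.
#' @keywords internal
permute_graph <- function(graph, perm) {
  n <- nrow(graph$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a1[k]; b <- graph$bonds$a2[k]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  atoms <- graph$atoms
  for (i in seq_len(n)) {
    if (!(atoms$parity[i] %in% c(1L, 2L))) next
    old_order <- sort(nbrs[[i]])            # neighbour order before
    if (.inversions(perm[old_order]) %% 2L == 1L) {
      atoms$parity[i] <- ifelse(atoms$parity[i] == 1L, 2L, 1L)
    }
  }
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  atoms <- atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- graph$bonds
  bonds$a1 <- perm[bonds$a1]
  bonds$a2 <- perm[bonds$a2]
  list(atoms = atoms, bonds = bonds)
}
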