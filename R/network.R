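#' Parse an atom-transition metabolic network
#'
#' Reads a plain-text network definition into an `mfa_network` object holding
#' metabolites, reactions, carbon atom transitions and the stoichiometric
#' matrix. The format is one reaction per line,
#'
#' ```
#' # comment
#' @boundary: Glc.ext MeOH.ext CO2.ext
#' pgi: Glc6P(abcdef) <-> Fru6P(abcdef)
#' das: Form(a) + Xul5P(bcdef) -> DHA(bca) + GA3P(def)
#' akgdh: AKG(abcde) -> Suc(bcde) + CO2(a) | Suc(edcb) + CO2(a)
#' ```
#'
#' `->` marks an irreversible reaction, `<->` a reversible one. The letters in
#' parentheses name carbon positions (1-based, left to right); every letter on
#' the left-hand side must appear exactly once on the right-hand side, which
#' enforces carbon balance. A `|` introduces an alternative right-hand side for
#' reactions forming a rotationally symmetric product (succinate, fumarate):
#' the line is expanded into two parallel reactions suffixed `.a` and `.b`
#' whose fluxes are structurally tied 1:1, so each atom map carries half of
#' the total flux. Metabolites listed in an `@boundary:` directive are feed or
#' sink species excluded from mass balancing.
#'
#' @param definition Character scalar: either a file path or the network text
#'   itself (detected by the presence of newlines / absence of a file).
#' @return An object of class `mfa_network` with elements
#'   \describe{
#'     \item{metabolites}{tibble with `id`, `n_carbons`, `is_boundary`, `pool`}
#'     \item{reactions}{tibble with `id`, `base_id`, `reversible`,
#'       `scrambled` (logical: part of a 1:1 symmetric-product pair)}
#'     \item{transitions}{named list of atom transitions per reaction}
#'     \item{S}{net stoichiometric matrix, balanced metabolites x reactions}
#'     \item{S_dir}{directed stoichiometric matrix, balanced metabolites x
#'       directed fluxes (reversible reactions contribute a forward and a
#'       backward column `<id>` and `<id>_b`)}
#'     \item{scramble_ties}{list of directed-flux name pairs tied 1:1}
#'   }
#' @examples
#' net <- parse_network("r1: A(ab) -> B(ab)\nr2: B(ab) -> C(ab)")
#' net$metabolites
#' @export
parse_network <- function(definition) {
  stopifnot(is.character(definition), length(definition) == 1L)
  if (!grepl("\n", definition) && file.exists(definition)) {
    lines <- readLines(definition, warn = FALSE)
  } else {
    lines <- strsplit(definition, "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)

  boundary_ids <- character()
  rxn_lines <- character()
  for (ln in lines) {
    if (ln == "") next
    if (startsWith(ln, "@boundary")) {
      ids <- strsplit(sub("^@boundary:?\\s*", "", ln), "\\s+")[[1]]
      boundary_ids <- union(boundary_ids, ids[ids != ""])
    } else {
      rxn_lines <- c(rxn_lines, ln)
    }
  }

  parse_side <- function(txt, rid) {
    terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
    out <- list()
    for (tm in terms) {
      tm <- trimws(tm)
      m <- regmatches(tm, regexec("^([A-Za-z0-9_.]+)\\(([A-Za-z0-9]*)\\)$", tm))[[1]]
      if (length(m) != 3) {
        stop(sprintf("reaction '%s': cannot parse species term '%s'", rid, tm),
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- list(met = m[2],
                                      atoms = strsplit(m[3], "")[[1]])
    }
    out
  }

  reactions <- list()
  transitions <- list()
  seen_ids <- character()

  for (ln in rxn_lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse reaction line: ", ln, call. = FALSE)
    rid <- m[2]
    body <- m[3]
    if (rid %in% seen_ids) stop("duplicate reaction id: ", rid, call. = FALSE)
    seen_ids <- c(seen_ids, rid)

    reversible <- grepl("<->", body, fixed = TRUE)
    sides <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("reaction '", rid, "': need one arrow", call. = FALSE)
    lhs <- parse_side(sides[1], rid)
    rhs_alts <- strsplit(sides[2], "|", fixed = TRUE)[[1]]
    if (length(rhs_alts) > 2) {
      stop("reaction '", rid, "': at most two alternative product maps", call. = FALSE)
    }
    rhs_list <- lapply(rhs_alts, parse_side, rid = rid)

    # carbon balance: LHS letters must map bijectively onto each RHS
    lhs_atoms <- unlist(lapply(lhs, `[[`, "atoms"))
    if (anyDuplicated(lhs_atoms)) {
      stop("reaction '", rid, "': duplicated carbon label on substrate side",
           call. = FALSE)
    }
    for (rhs in rhs_list) {
      rhs_atoms <- unlist(lapply(rhs, `[[`, "atoms"))
      if (length(rhs_atoms) != length(lhs_atoms) ||
          anyDuplicated(rhs_atoms) ||
          !setequal(lhs_atoms, rhs_atoms)) {
        stop("reaction '", rid, "': carbon count/label mismatch between sides",
             call. = FALSE)
      }
    }

    sub_ids <- if (length(rhs_list) == 1L) rid else paste0(rid, c(".a", ".b"))
    for (k in seq_along(rhs_list)) {
      reactions[[length(reactions) + 1L]] <- tibble::tibble(
        id = sub_ids[k], base_id = rid, reversible = reversible,
        scrambled = length(rhs_list) > 1L)
      transitions[[sub_ids[k]]] <- list(subs = lhs, prods = rhs_list[[k]])
    }
  }

  reactions <- dplyr::bind_rows(reactions)
  if (nrow(reactions) == 0) stop("network definition contains no reactions", call. = FALSE)

  # metabolite table; check carbon-count consistency
  met_carbons <- list()
  for (rid in reactions$id) {
    tr <- transitions[[rid]]
    for (sp in c(tr$subs, tr$prods)) {
      n <- length(sp$atoms)
      if (!is.null(met_carbons[[sp$met]]) && met_carbons[[sp$met]] != n) {
        stop("metabolite '", sp$met, "' has inconsistent carbon counts",
             call. = FALSE)
      }
      met_carbons[[sp$met]] <- n
    }
  }
  metabolites <- tibble::tibble(
    id = names(met_carbons),
    n_carbons = unlist(met_carbons, use.names = FALSE),
    is_boundary = names(met_carbons) %in% boundary_ids,
    pool = NA_real_)

  unknown_boundary <- setdiff(boundary_ids, metabolites$id)
  if (length(unknown_boundary)) {
    stop("boundary species not used in any reaction: ",
         paste(unknown_boundary, collapse = ", "), call. = FALSE)
  }

  net <- structure(list(metabolites = metabolites,
                        reactions = reactions,
                        transitions = transitions),
                   class = "mfa_network")
  net$S <- stoich_matrix(net, directed = FALSE)
  net$S_dir <- stoich_matrix(net, directed = TRUE)
  net$scramble_ties <- scramble_tie_pairs(net)
  net
}

#' Directed flux names of a network
#'
#' Each irreversible reaction contributes one directed flux named after the
#' reaction; each reversible reaction contributes `<id>` (forward) and
#' `<id>_b` (backward).
#' @param network An `mfa_network`.
#' @return Character vector of directed flux names.
#' @export
directed_fluxes <- function(network) {
  unlist(lapply(seq_len(nrow(network$reactions)), function(i) {
    id <- network$reactions$id[i]
    if (network$reactions$reversible[i]) c(id, paste0(id, "_b")) else id
  }))
}

stoich_matrix <- function(network, directed = FALSE) {
  bal <- network$metabolites$id[!network$metabolites$is_boundary]
  cols <- if (directed) directed_fluxes(network) else network$reactions$id
  S <- matrix(0, length(bal), length(cols), dimnames = list(bal, cols))
  for (i in seq_len(nrow(network$reactions))) {
    id <- network$reactions$id[i]
    tr <- network$transitions[[id]]
    col <- numeric(length(bal)); names(col) <- bal
    for (sp in tr$subs) if (sp$met %in% bal) col[sp$met] <- col[sp$met] - 1
    for (sp in tr$prods) if (sp$met %in% bal) col[sp$met] <- col[sp$met] + 1
    S[, id] <- col
    if (directed && network$reactions$reversible[i]) S[, paste0(id, "_b")] <- -col
  }
  S
}

scramble_tie_pairs <- function(network) {
  ties <- list()
  groups <- unique(network$reactions$base_id[network$reactions$scrambled])
  for (g in groups) {
    ids <- network$reactions$id[network$reactions$base_id == g]
    rev <- network$reactions$reversible[network$reactions$base_id == g][1]
    ties[[length(ties) + 1L]] <- ids
    if (rev) ties[[length(ties) + 1L]] <- paste0(ids, "_b")
  }
  ties
}

#' @export
print.mfa_network <- function(x, ...) {
  n_bal <- sum(!x$metabolites$is_boundary)
  cat("<mfa_network> ", n_bal, " balanced metabolites (",
      sum(x$metabolites$is_boundary), " boundary), ",
      ncol(x$S_dir), " reactions incl. bidirectional fluxes (",
      nrow(x$reactions), " net)\n", sep = "")
  invisible(x)
}

#' Summarize a metabolic network
#'
#' @param object An `mfa_network`.
#' @param ... Unused.
#' @return A one-row tibble with metabolite and reaction counts. The
#'   `n_reactions` column counts directed fluxes, i.e. both directions of a
#'   reversible reaction and both members of a symmetric-product pair.
#' @export
summary.mfa_network <- function(object, ...) {
  tibble::tibble(
    n_metabolites = sum(!object$metabolites$is_boundary),
    n_boundary = sum(object$metabolites$is_boundary),
    n_reactions = ncol(object$S_dir),
    n_net_reactions = nrow(object$reactions),
    n_reversible = sum(object$reactions$reversible))
}

#' Assemble a flux distribution
#'
#' Builds a `flux_distribution` tibble (one row per reaction) from named
#' vectors of net and exchange fluxes, in mmol/gCDW/h. Forward and backward
#' fluxes are derived as `fwd = max(net, 0) + exchange` and
#' `bwd = max(-net, 0) + exchange`.
#'
#' @param network An `mfa_network`.
#' @param net Named numeric vector of net fluxes (one per reaction; signed).
#' @param exchange Named numeric vector of exchange fluxes for reversible
#'   reactions (non-negative). Missing entries default to 0.
#' @return A tibble of class `flux_distribution` with columns `reaction`,
#'   `net`, `exchange`, `fwd`, `bwd`.
#' @export
flux_distribution <- function(network, net, exchange = NULL) {
  ids <- network$reactions$id
  missing <- setdiff(ids, names(net))
  if (length(missing)) {
    stop("missing net flux for reaction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  net <- net[ids]
  exch <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(exchange)) exch[names(exchange)] <- exchange
  if (any(exch < 0)) stop("exchange fluxes must be >= 0", call. = FALSE)
  irrev <- !network$reactions$reversible
  if (any(exch[irrev] != 0)) {
    stop("irreversible reactions cannot carry exchange flux", call. = FALSE)
  }
  if (any(net[irrev] < -1e-9)) {
    stop("irreversible reactions require net flux >= 0: ",
         paste(ids[irrev][net[irrev] < -1e-9], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    reaction = ids,
    net = unname(net),
    exchange = unname(exch),
    fwd = pmax(unname(net), 0) + unname(exch),
    bwd = pmax(-unname(net), 0) + unname(exch))
  class(out) <- c("flux_distribution", class(out))
  out
}

#' Convert a flux distribution to the directed-flux vector
#'
#' @param network An `mfa_network`.
#' @param fluxes A `flux_distribution`.
#' @return Named numeric vector over [directed_fluxes()] of the network.
#' @export
directed_vector <- function(network, fluxes) {
  w <- stats::setNames(numeric(ncol(network$S_dir)), colnames(network$S_dir))
  for (i in seq_len(nrow(fluxes))) {
    id <- fluxes$reaction[i]
    rev <- network$reactions$reversible[network$reactions$id == id]
    if (rev) {
      w[id] <- fluxes$fwd[i]
      w[paste0(id, "_b")] <- fluxes$bwd[i]
    } else {
      w[id] <- fluxes$net[i]
    }
  }
  w
}

directed_to_distribution <- function(network, w) {
  ids <- network$reactions$id
  rev <- network$reactions$reversible
  net <- exch <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    if (rev[i]) {
      f <- w[[ids[i]]]; b <- w[[paste0(ids[i], "_b")]]
      net[i] <- f - b
      exch[i] <- min(f, b)
    } else {
      net[i] <- w[[ids[i]]]
    }
  }
  flux_distribution(network, net, exch)
}

#' Steady-state residual of a flux distribution
#'
#' Computes the largest absolute net imbalance `max |S v_net|` over the
#' balanced metabolites.
#'
#' @param network An `mfa_network`.
#' @param fluxes A `flux_distribution` covering every reaction.
#' @param tol Tolerance below which the distribution is declared balanced.
#' @return The residual norm, with attribute `balanced` (logical).
#' @export
validate_steady_state <- function(network, fluxes, tol = 1e-8) {
  ids <- network$reactions$id
  if (!all(ids %in% fluxes$reaction)) {
    stop("flux distribution does not cover every reaction", call. = FALSE)
  }
  v <- stats::setNames(fluxes$net, fluxes$reaction)[ids]
  if (anyNA(v)) stop("missing flux value", call. = FALSE)
  res <- max(abs(network$S %*% v))
  attr(res, "balanced") <- res <= tol
  res
}

# ---- constraint handling -----------------------------------------------------

#' Read a flux constraint set
#'
#' Constraint files are YAML with two optional keys: `fixed`, a mapping from
#' reaction id to a fixed net flux value (mmol/gCDW/h), and `ties`, a list of
#' strings `"idA == idB"` forcing equal net fluxes (used e.g. to tie an
#' unlabeled pyruvate source to its sink so that carbon balance is preserved).
#'
#' @param path Path to the YAML file.
#' @return A list with elements `fixed` (named numeric) and `ties` (list of
#'   character pairs), of class `flux_constraints`.
#' @export
read_constraints <- function(path) {
  y <- yaml::read_yaml(path)
  fixed <- if (!is.null(y$fixed)) unlist(y$fixed) else stats::setNames(numeric(0), character(0))
  ties <- lapply(y$ties %||% list(), function(s) {
    parts <- trimws(strsplit(s, "==", fixed = TRUE)[[1]])
    if (length(parts) != 2) stop("cannot parse tie: ", s, call. = FALSE)
    parts
  })
  structure(list(fixed = fixed, ties = ties), class = "flux_constraints")
}

#' Construct a flux constraint set in code
#'
#' @param fixed Named numeric vector of fixed net fluxes.
#' @param ties List of length-2 character vectors naming tied reactions.
#' @return A `flux_constraints` object.
#' @export
flux_constraints <- function(fixed = NULL, ties = list()) {
  fixed <- if (is.null(fixed)) stats::setNames(numeric(0), character(0)) else fixed
  structure(list(fixed = fixed, ties = ties), class = "flux_constraints")
}

# rows of the constraint system in directed-flux space, plus rhs
constraint_rows <- function(network, constraints) {
  wn <- colnames(network$S_dir)
  rev_ids <- network$reactions$id[network$reactions$reversible]
  net_row <- function(id) {
    if (!id %in% network$reactions$id) {
      stop("constraint names unknown reaction: ", id, call. = FALSE)
    }
    r <- stats::setNames(numeric(length(wn)), wn)
    r[id] <- 1
    if (id %in% rev_ids) r[paste0(id, "_b")] <- -1
    r
  }
  rows <- list(); rhs <- numeric(0); labels <- character(0)
  for (id in names(constraints$fixed)) {
    rows[[length(rows) + 1L]] <- net_row(id)
    rhs <- c(rhs, constraints$fixed[[id]])
    labels <- c(labels, paste0("fixed:", id))
  }
  for (tie in constraints$ties) {
    rows[[length(rows) + 1L]] <- net_row(tie[1]) - net_row(tie[2])
    rhs <- c(rhs, 0)
    labels <- c(labels, paste0("tie:", tie[1], "==", tie[2]))
  }
  # structural 1:1 ties of symmetric-product pairs act on directed fluxes
  for (pair in network$scramble_ties) {
    r <- stats::setNames(numeric(length(wn)), wn)
    r[pair[1]] <- 1; r[pair[2]] <- -1
    rows[[length(rows) + 1L]] <- r
    rhs <- c(rhs, 0)
    labels <- c(labels, paste0("scramble:", pair[1], "==", pair[2]))
  }
  A <- do.call(rbind, rows)
  if (is.null(A)) A <- matrix(0, 0, length(wn), dimnames = list(NULL, wn))
  rownames(A) <- labels
  list(A = A, b = rhs)
}

#' Free-flux basis of a constrained network
#'
#' Determines how many (and which) directed fluxes can be chosen freely once
#' the steady-state balances and the constraint set are imposed, and returns a
#' completion map from free fluxes to a full flux distribution. The basis
#' dimension is `n_directed - rank([S_dir; C])` where `C` stacks the fixed
#' values, explicit net-flux ties and the structural 1:1 ties of
#' symmetric-product reaction pairs.
#'
#' @param network An `mfa_network`.
#' @param constraints A `flux_constraints` object (or `NULL` for none).
#' @return An object of class `flux_basis` with elements `free` (names of the
#'   free directed fluxes), `n_free`, the null-space basis `N`, a particular
#'   solution `w0`, and the constraint matrix used.
#' @export
free_flux_basis <- function(network, constraints = NULL) {
  if (is.null(constraints)) constraints <- flux_constraints()
  cr <- constraint_rows(network, constraints)
  A <- rbind(network$S_dir, cr$A)
  b <- c(rep(0, nrow(network$S_dir)), cr$b)

  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  # consistency: b must lie in the column space of A
  if (r < nrow(A)) {
    resid <- t(sv$u[, seq_len(nrow(A)) > r, drop = FALSE]) %*% b
    if (any(abs(resid) > 1e-8 * max(1, max(abs(b))))) {
      stop("constraint set is inconsistent with the steady-state balances",
           call. = FALSE)
    }
  }
  n_free <- ncol(A) - r
  if (n_free < 0) stop("over-constrained flux system", call. = FALSE)
  N <- sv$v[, seq_len(ncol(A)) > r, drop = FALSE]
  rownames(N) <- colnames(A)
  # minimum-norm particular solution
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  w0 <- sv$v[, seq_len(r), drop = FALSE] %*%
    (d_inv[seq_len(r)] * (t(sv$u[, seq_len(r), drop = FALSE]) %*% b))
  w0 <- stats::setNames(drop(w0), colnames(A))

  free <- character(0)
  if (n_free > 0) {
    piv <- qr(t(N), LAPACK = TRUE)$pivot[seq_len(n_free)]
    free <- colnames(A)[sort(piv)]
  }
  structure(list(network = network, constraints = constraints,
                 free = free, n_free = n_free, N = N, w0 = w0,
                 A = A, b = b),
            class = "flux_basis")
}

#' @export
print.flux_basis <- function(x, ...) {
  cat("<flux_basis> ", x$n_free, " free fluxes\n", sep = "")
  if (x$n_free) cat(" ", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Complete a flux distribution from free-flux values
#'
#' Given values for the free directed fluxes of a [free_flux_basis()], solves
#' for the unique full flux vector satisfying the steady-state balances and
#' all constraints, and returns it as a `flux_distribution`.
#'
#' @param basis A `flux_basis`.
#' @param free_values Named numeric vector covering `basis$free`.
#' @param nonneg_tol Directed fluxes more negative than `-nonneg_tol` raise an
#'   error (directed fluxes are physically non-negative); small negative
#'   round-off is clamped to zero.
#' @return A `flux_distribution`.
#' @export
complete_fluxes <- function(basis, free_values, nonneg_tol = 1e-6) {
  if (basis$n_free == 0) {
    w <- basis$w0
  } else {
    if (!all(basis$free %in% names(free_values))) {
      stop("free_values must cover: ", paste(basis$free, collapse = ", "),
           call. = FALSE)
    }
    f <- free_values[basis$free]
    Nf <- basis$N[basis$free, , drop = FALSE]
    alpha <- solve(Nf, f - basis$w0[basis$free])
    w <- basis$w0 + drop(basis$N %*% alpha)
  }
  if (any(w < -nonneg_tol)) {
    bad <- names(w)[w < -nonneg_tol]
    stop("completion yields negative directed flux(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- pmax(w, 0)
  directed_to_distribution(basis$network, w)
}
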