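#' Define a string-chemistry universe
#'
#' A chemical universe is the complete set of metabolites (all strings of
#' length 1 to `max_len` over an alphabet of monomer characters) together with
#' all pairwise condensation/splitting reactions among them. Universes are the
#' starting point for everything else in the package: stoichiometric matrices,
#' flux balance models, pruning, and ensembles.
#'
#' @param n_monomers Number of distinct monomer characters (the alphabet size
#'   `A`). Ignored when `alphabet` is given.
#' @param max_len Maximum string length `L` (positive integer).
#' @param alphabet Optional character vector of distinct single characters to
#'   use as the alphabet; defaults to the first `n_monomers` lowercase letters.
#'
#' @return An object of class `chem_universe` with fields `alphabet`,
#'   `n_monomers` and `max_len`.
#' @examples
#' u <- chem_universe(2, 3)
#' count_metabolites(2, 3)
#' enumerate_metabolites(u)
#' @export
chem_universe <- function(n_monomers = NULL, max_len, alphabet = NULL) {
  if (is.null(alphabet)) {
    if (is.null(n_monomers)) {
      stop("supply either `n_monomers` or `alphabet`", call. = FALSE)
    }
    check_count(n_monomers, "n_monomers")
    if (n_monomers > 26) {
      stop("default alphabet supports up to 26 monomers; pass `alphabet`",
           call. = FALSE)
    }
    alphabet <- letters[seq_len(n_monomers)]
  } else {
    alphabet <- as.character(alphabet)
    if (any(nchar(alphabet) != 1L)) {
      stop("`alphabet` must contain single characters", call. = FALSE)
    }
    if (anyDuplicated(alphabet)) {
      stop("`alphabet` characters must be pairwise distinct", call. = FALSE)
    }
    if (length(alphabet) < 1L) stop("`alphabet` must be non-empty", call. = FALSE)
  }
  check_count(max_len, "max_len")
  structure(
    list(alphabet = alphabet,
         n_monomers = length(alphabet),
         max_len = as.integer(max_len)),
    class = "chem_universe")
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a positive integer (got %s)", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
#' @method print chem_universe
print.chem_universe <- function(x, ...) {
  cat(sprintf(
    "<chem_universe> A = %d (alphabet: %s), L = %d\n  %s metabolites, %s reactions\n",
    x$n_monomers, paste(x$alphabet, collapse = ""), x$max_len,
    format(count_metabolites(x$n_monomers, x$max_len), big.mark = ","),
    format(count_reactions(x$n_monomers, x$max_len), big.mark = ",")))
  invisible(x)
}

#' Closed-form universe sizes
#'
#' Number of metabolites and reactions in the complete universe with `A`
#' monomer types and maximum length `L`. The metabolite count is
#' \eqn{\sum_{i=1}^{L} A^i} (equal to \eqn{A(A^L-1)/(A-1)} for `A != 1` and to
#' `L` for `A = 1`); the reaction count is \eqn{\sum_{i=1}^{L} (i-1)A^i}
#' (equal to \eqn{A((L-1)A^{L+1} - LA^L + A)/(A-1)^2} for `A != 1` and to
#' `L(L-1)/2` for `A = 1`), one reaction per internal split position of every
#' string of length at least 2.
#'
#' Counts are accumulated with exact integer arithmetic and refuse to return
#' anything beyond 2^53, where doubles stop being exact.
#'
#' @param A Alphabet size (positive integer).
#' @param L Maximum string length (positive integer).
#' @return A non-negative count (numeric, integer-valued).
#' @examples
#' count_metabolites(3, 2)  # 12
#' count_reactions(3, 3)    # 63
#' @export
count_metabolites <- function(A, L) {
  check_count(A, "A"); check_count(L, "L")
  tot <- 0; p <- 1
  for (i in seq_len(L)) {
    p <- p * A
    tot <- tot + p
    if (tot > 2^53) stop("metabolite count exceeds 2^53; not exactly representable",
                         call. = FALSE)
  }
  tot
}

#' @rdname count_metabolites
#' @export
count_reactions <- function(A, L) {
  check_count(A, "A"); check_count(L, "L")
  tot <- 0; p <- 1
  for (i in seq_len(L)) {
    p <- p * A
    tot <- tot + (i - 1) * p
    if (tot > 2^53) stop("reaction count exceeds 2^53; not exactly representable",
                         call. = FALSE)
  }
  tot
}

#' Enumerate all metabolites of a universe
#'
#' Returns every string of length 1 to `L` over the alphabet, in deterministic
#' length-major then lexicographic (alphabet-order) order.
#'
#' @param universe A [chem_universe()].
#' @return A tibble with columns `id` and `length`.
#' @export
enumerate_metabolites <- function(universe) {
  stopifnot(inherits(universe, "chem_universe"))
  out <- vector("list", universe$max_len)
  cur <- universe$alphabet
  out[[1L]] <- cur
  if (universe$max_len > 1L) {
    for (l in 2:universe$max_len) {
      # extend each length-(l-1) string by every monomer; row-major keeps
      # lexicographic order
      cur <- as.vector(t(outer(cur, universe$alphabet, paste0)))
      out[[l]] <- cur
    }
  }
  ids <- unlist(out, use.names = FALSE)
  tibble(id = ids, length = nchar(ids))
}

#' Enumerate all condensation/splitting reactions of a universe
#'
#' One reversible reaction per (product string, internal split position):
#' `left + right <-> product` with `left = product[1:pos]` and
#' `right = product[(pos+1):len]`. Split positions that yield the same
#' unordered reactant pair (e.g. positions 1 and 3 of `"aaaa"`) are distinct
#' reactions, matching the combinatorial count of [count_reactions()]; set
#' `dedupe = TRUE` to collapse them.
#'
#' Order is deterministic: products in metabolite enumeration order, then
#' ascending split position.
#'
#' @param universe A [chem_universe()].
#' @param dedupe Collapse reactions with identical stoichiometry (default
#'   `FALSE`).
#' @return A tibble with columns `id`, `product`, `split_pos`, `left`, `right`.
#' @export
enumerate_reactions <- function(universe, dedupe = FALSE) {
  stopifnot(inherits(universe, "chem_universe"))
  mets <- enumerate_metabolites(universe)
  prods <- mets$id[mets$length >= 2L]
  if (length(prods) == 0L) {
    return(tibble(id = character(), product = character(),
                  split_pos = integer(), left = character(), right = character()))
  }
  lens <- nchar(prods)
  product <- rep(prods, lens - 1L)
  split_pos <- unlist(lapply(lens - 1L, seq_len), use.names = FALSE)
  left <- substr(product, 1L, split_pos)
  right <- substr(product, split_pos + 1L, nchar(product))
  rxn <- tibble(
    id = paste0(left, "+", right, "->", product),
    product = product, split_pos = split_pos, left = left, right = right)
  if (dedupe) {
    key <- paste(pmin(rxn$left, rxn$right), pmax(rxn$left, rxn$right), rxn$product)
    rxn <- rxn[!duplicated(key), ]
  }
  rxn
}

#' Build the stoichiometric matrix of a universe
#'
#' Rows are metabolites (enumeration order), columns are reactions
#' (enumeration order). A condensation column has -1 for each distinct
#' reactant (-2 when the two reactants are the same string) and +1 for the
#' product; every column conserves each monomer character exactly.
#'
#' @param universe A [chem_universe()].
#' @param reactions Optional subset of reaction ids to include as columns
#'   (order preserved from the universe enumeration).
#' @return A sparse [Matrix::sparseMatrix()] (`dgCMatrix`) with dimnames
#'   `(metabolite id, reaction id)`.
#' @export
build_stoichiometric_matrix <- function(universe, reactions = NULL) {
  stopifnot(inherits(universe, "chem_universe"))
  mets <- enumerate_metabolites(universe)$id
  rxn <- enumerate_reactions(universe)
  if (!is.null(reactions)) {
    missing <- setdiff(reactions, rxn$id)
    if (length(missing)) {
      stop("unknown reaction id(s): ", paste(head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    rxn <- rxn[rxn$id %in% reactions, ]
  }
  met_idx <- setNames(seq_along(mets), mets)
  n_r <- nrow(rxn)
  same <- rxn$left == rxn$right
  i <- c(met_idx[rxn$product],
         met_idx[rxn$left],
         met_idx[rxn$right[!same]])
  j <- c(seq_len(n_r), seq_len(n_r), seq_len(n_r)[!same])
  x <- c(rep(1, n_r), ifelse(same, -2, -1), rep(-1, sum(!same)))
  Matrix::sparseMatrix(i = unname(i), j = j, x = x,
                       dims = c(length(mets), n_r),
                       dimnames = list(mets, rxn$id))
}

#' Write a stoichiometric matrix as dense CSV
#'
#' First column holds metabolite ids, header row holds reaction ids.
#'
#' @param S A stoichiometric matrix (as from [build_stoichiometric_matrix()]).
#' @param path Output file path.
#' @export
write_stoich_csv <- function(S, path) {
  df <- as.data.frame(as.matrix(S))
  df <- cbind(metabolite = rownames(S), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stoich_csv
#' @export
read_stoich_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Write a stoichiometric matrix as sparse triplets
#'
#' Tab-separated columns `metabolite_id`, `reaction_id`, `coefficient`; one
#' row per nonzero entry.
#'
#' @inheritParams write_stoich_csv
#' @export
write_stoich_triplets <- function(S, path) {
  tr <- Matrix::summary(methods::as(S, "TsparseMatrix"))
  out <- data.frame(metabolite_id = rownames(S)[tr$i],
                    reaction_id = colnames(S)[tr$j],
                    coefficient = tr$x)
  out <- out[order(tr$j, tr$i), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
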