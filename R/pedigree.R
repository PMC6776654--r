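#' Expected relatedness matrix from twin pedigree information
#'
#' Builds the square symmetric matrix of pedigree-expected relatedness
#' (twice the kinship coefficient): 1 on the diagonal, 1 for monozygotic
#' co-twins, 0.5 for dizygotic co-twins, 0 across families. Storing
#' relatedness rather than kinship means the genetic covariance of the
#' variance-component model is `sigma_g^2 * K` directly.
#'
#' @param pedigree data.frame with columns `family_id`, `individual_id`
#'   and `zygosity` (`"MZ"`, `"DZ"` or `NA` for singletons).
#' @return named symmetric matrix indexed by `individual_id`. MZ blocks are
#'   singular (eigenvalues 0 and 2); downstream solvers must therefore use
#'   an eigendecomposition rather than inversion.
#' @export
kinship_matrix <- function(pedigree) {
  validate_pedigree(pedigree)
  ids <- pedigree$individual_id
  n <- length(ids)
  K <- diag(1, n)
  dimnames(K) <- list(ids, ids)
  for (fam in unique(pedigree$family_id)) {
    rows <- which(pedigree$family_id == fam)
    if (length(rows) == 2) {
      zy <- pedigree$zygosity[rows[1]]
      rel <- if (!is.na(zy) && zy == "MZ") 1 else if (!is.na(zy) && zy == "DZ") 0.5 else 0
      K[rows[1], rows[2]] <- rel
      K[rows[2], rows[1]] <- rel
    }
  }
  K
}

#' Family-block relatedness matrix
#'
#' Relatedness 1 between all members of the same family, equivalent to a
#' random-intercept-per-family model when used in the variance-component
#' fitter. Used for the dialogue-stage linear mixed model.
#'
#' @param family_ids per-sample family labels.
#' @param ids optional individual ids for dimnames.
#' @return named symmetric matrix.
#' @export
family_matrix <- function(family_ids, ids = names(family_ids)) {
  n <- length(family_ids)
  K <- outer(family_ids, family_ids, "==") * 1
  diag(K) <- 1
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  K
}

validate_pedigree <- function(pedigree) {
  need <- c("family_id", "individual_id", "zygosity")
  if (!all(need %in% names(pedigree))) {
    stop("pedigree must have columns family_id, individual_id, zygosity")
  }
  if (anyDuplicated(pedigree$individual_id)) {
    dup <- pedigree$individual_id[duplicated(pedigree$individual_id)][1]
    stop(sprintf("duplicate individual_id in pedigree: %s", dup))
  }
  twin <- !is.na(pedigree$zygosity) & pedigree$zygosity %in% c("MZ", "DZ")
  for (fam in unique(pedigree$family_id[twin])) {
    sz <- sum(pedigree$family_id == fam)
    if (sz != 2) {
      stop(sprintf("twin family %s has %d members; MZ/DZ families must have exactly 2",
                   fam, sz))
    }
  }
  invisible(pedigree)
}

# Pair structure of a relatedness matrix with blocks of size <= 2:
# partner index (NA for singletons) and the off-diagonal value. NULL when
# the matrix has larger blocks (general K).
kinship_structure <- function(K) {
  n <- nrow(K)
  off <- K
  diag(off) <- 0
  nz <- which(off != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] < nz[, 2], , drop = FALSE]
  partner <- rep(NA_integer_, n)
  kval <- rep(NA_real_, n)
  if (nrow(nz) > 0) {
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1]; j <- nz[r, 2]
      if (!is.na(partner[i]) || !is.na(partner[j])) return(NULL)
      partner[i] <- j; partner[j] <- i
      kval[i] <- kval[j] <- off[i, j]
    }
  }
  list(partner = partner, kval = kval, n = n)
}

# Rotation object for the subset `pos` (integer positions) of a pair
# structure: eigenbasis of K[pos, pos] built analytically from the 2x2
# twin blocks. O(length(pos)).
rotation_from_structure <- function(st, pos = seq_len(st$n)) {
  rank_of <- integer(st$n)
  rank_of[pos] <- seq_along(pos)
  partner <- st$partner[pos]                      # original index or NA
  partner_rank <- ifelse(is.na(partner), 0L, rank_of[pmax(partner, 1L)])
  paired <- partner_rank > 0L
  first <- paired & pos < partner                 # lower member of each pair
  p1 <- which(first)
  p2 <- partner_rank[first]
  sg <- which(!paired)
  k <- st$kval[pos][p1]
  values <- c(1 + k, 1 - k, rep(1, length(sg)))
  rotate <- function(M) {
    M <- as.matrix(M)
    rbind((M[p1, , drop = FALSE] + M[p2, , drop = FALSE]) / sqrt(2),
          (M[p1, , drop = FALSE] - M[p2, , drop = FALSE]) / sqrt(2),
          M[sg, , drop = FALSE])
  }
  list(values = values, rotate = rotate)
}

# Eigen-structure of a relatedness matrix, exploiting the twin-cohort
# block structure (blocks of size <= 2) when present. Returns
# list(values, rotate) where rotate(M) computes t(U) %*% M for the
# orthonormal eigenbasis U. Falls back to a dense eigendecomposition for
# general K.
kinship_rotation <- function(K) {
  st <- kinship_structure(K)
  if (!is.null(st)) return(rotation_from_structure(st))
  ev <- eigen(K, symmetric = TRUE)
  list(values = ev$values, rotate = function(M) crossprod(ev$vectors, as.matrix(M)))
}
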