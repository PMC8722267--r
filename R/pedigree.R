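#' Construct and validate a pedigree
#'
#' Builds a pedigree object from animal/sire/dam triples. Animals must be
#' ordered so that parents precede their offspring; unknown parents are coded
#' 0 (or NA). Inbreeding coefficients are computed with the Meuwissen-Luo
#' algorithm and stored on the object.
#'
#' @param id integer or character vector of animal identifiers (unique).
#' @param sire,dam parent identifiers; 0 or NA for unknown.
#' @param sex optional factor/character vector ("M"/"F"), kept as metadata.
#' @param generation optional integer vector, kept as metadata.
#' @return An object of class `lv_pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam` (integer indices, 0 = unknown), `f` (inbreeding),
#'   plus any metadata columns, and attribute `labels` holding original ids.
#' @export
pedigree <- function(id, sire, dam, sex = NULL, generation = NULL) {
  n <- length(id)
  if (length(sire) != n || length(dam) != n) {
    stop("id, sire and dam must have equal length", call. = FALSE)
  }
  if (anyDuplicated(id)) stop("duplicated animal ids in pedigree", call. = FALSE)
  labels <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[is.na(sire) | sire %in% c("0", "")] <- NA
  dam[is.na(dam) | dam %in% c("0", "")] <- NA
  si <- match(sire, labels)
  di <- match(dam, labels)
  if (any(!is.na(sire) & is.na(si)) || any(!is.na(dam) & is.na(di))) {
    stop("parent id not present in pedigree", call. = FALSE)
  }
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  idx <- seq_len(n)
  if (any(si >= idx) || any(di >= idx)) {
    stop("pedigree not ordered: every parent must precede its offspring",
         call. = FALSE)
  }
  ped <- data.frame(id = idx, sire = si, dam = di)
  ped$f <- inbreeding_ml(si, di)
  if (!is.null(sex)) ped$sex <- sex
  if (!is.null(generation)) ped$generation <- generation
  attr(ped, "labels") <- labels
  class(ped) <- c("lv_pedigree", "data.frame")
  ped
}

#' @export
print.lv_pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals;",
      sum(x$sire == 0 & x$dam == 0), "founders; mean F =",
      signif(mean(x$f), 3), "\n")
  invisible(x)
}

# Meuwissen & Luo (1992) inbreeding coefficients.
# si, di: integer parent indices (0 = unknown), parents precede offspring.
inbreeding_ml <- function(si, di) {
  n <- length(si)
  f <- numeric(n)
  # L: within-animal workspace of additive relationship contributions
  point <- integer(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s == 0L || d == 0L) {
      f[i] <- 0
      next
    }
    # trace ancestors of i, accumulating path coefficients L; then
    # a_ii = sum_j L_j^2 D_j (including i's own Mendelian term) = 1 + F_i
    L <- numeric(i)
    L[s] <- L[s] + 0.5
    L[d] <- L[d] + 0.5
    acc <- 0.5 - 0.25 * (f[s] + f[d])  # own Mendelian sampling variance
    for (j in (i - 1L):1L) {
      if (L[j] == 0) next
      sj <- si[j]; dj <- di[j]
      dj2 <- 0.5 - 0.25 * ((if (sj > 0L) f[sj] else -1) +
                           (if (dj > 0L) f[dj] else -1))
      acc <- acc + L[j]^2 * dj2
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * L[j]
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * L[j]
    }
    f[i] <- acc - 1
  }
  f
}

#' Inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for (Mendelian sampling
#' variances from Meuwissen-Luo inbreeding coefficients).
#'
#' @param ped an `lv_pedigree`.
#' @param use_inbreeding logical; if `FALSE`, F is taken as zero everywhere.
#' @return sparse symmetric matrix (`dsCMatrix`) of dimension n x n.
#' @export
build_a_inverse <- function(ped, use_inbreeding = TRUE) {
  stopifnot(inherits(ped, "lv_pedigree"))
  n <- nrow(ped)
  si <- ped$sire; di <- ped$dam
  f <- if (use_inbreeding) ped$f else numeric(n)
  # for each animal add alpha * outer(k, k) with k = (1, -0.5, -0.5) on
  # (i, s, d); unknown parents contribute nothing
  fs <- ifelse(si > 0L, f[pmax(si, 1L)], -1)
  fd <- ifelse(di > 0L, f[pmax(di, 1L)], -1)
  msv <- 0.5 - 0.25 * (fs + fd)   # = 1 if both unknown, 0.75 one known
  alpha <- 1 / msv
  idx <- rbind(seq_len(n), si, di)          # 3 x n, 0 = absent
  w <- c(1, -0.5, -0.5)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (p in 1:3) {
    for (q in 1:3) {
      keep <- idx[p, ] > 0L & idx[q, ] > 0L
      ii <- c(ii, idx[p, keep])
      jj <- c(jj, idx[q, keep])
      xx <- c(xx, alpha[keep] * w[p] * w[q])
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense construction, intended for small pedigrees (oracle checks, PEV
#' scaling). For large pedigrees use [build_a_inverse()].
#'
#' @param ped an `lv_pedigree`.
#' @return dense symmetric matrix.
#' @export
a_matrix <- function(ped) {
  stopifnot(inherits(ped, "lv_pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n)
  si <- ped$sire; di <- ped$dam
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}

#' Pedigree depth
#'
#' Number of known ancestral generations plus one: founders have depth 1,
#' any other animal 1 + max(depth of known parents).
#'
#' @param ped an `lv_pedigree`.
#' @return integer vector of per-animal depths.
#' @export
pedigree_depth <- function(ped) {
  stopifnot(inherits(ped, "lv_pedigree"))
  n <- nrow(ped)
  depth <- integer(n)
  for (i in seq_len(n)) {
    ds <- if (ped$sire[i] > 0L) depth[ped$sire[i]] else 0L
    dd <- if (ped$dam[i] > 0L) depth[ped$dam[i]] else 0L
    depth[i] <- 1L + max(ds, dd)
  }
  depth
}
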