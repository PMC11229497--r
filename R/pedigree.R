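#' Build a pedigree
#'
#' A sire/dam DAG with optional per-animal genotype labels. Parents that are
#' not themselves rows are added as founders. Cycles (an animal being its
#' own ancestor) are an error. Unknown parents are treated as unique,
#' non-inbred founders.
#'
#' @param id Animal identifiers (unique).
#' @param sire,dam Parent identifiers or `NA` when unknown.
#' @param sex Optional sex labels.
#' @param genotype Optional labels in `hom_alt`, `het`, `hom_ref`,
#'   `unknown` for carrier tracing.
#' @return An object of class `pedigree` (a data.frame).
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex = NULL, genotype = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("animal ids must be unique")
  n <- length(id)
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  d <- data.frame(id = c(id, extra),
                  sire = c(sire, rep(NA_character_, length(extra))),
                  dam = c(dam, rep(NA_character_, length(extra))),
                  stringsAsFactors = FALSE)
  d$sex <- if (!is.null(sex)) c(as.character(rep_len(sex, n)),
                                rep(NA_character_, length(extra)))
           else NA_character_
  d$genotype <- if (!is.null(genotype))
    c(as.character(rep_len(genotype, n)), rep("unknown", length(extra)))
  else "unknown"
  d$genotype[is.na(d$genotype)] <- "unknown"
  if (!all(d$genotype %in% c("hom_alt", "het", "hom_ref", "unknown")))
    stop("genotype labels must be hom_alt, het, hom_ref or unknown")
  class(d) <- c("pedigree", "data.frame")
  assert_acyclic(d)
  d
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x), "animal(s),",
      sum(is.na(x$sire) & is.na(x$dam)), "founder(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

assert_acyclic <- function(ped) {
  # Kahn-style topological elimination over parent links
  remaining <- ped$id
  repeat {
    par <- c(ped$sire[match(remaining, ped$id)],
             ped$dam[match(remaining, ped$id)])
    is_parent <- remaining %in% stats::na.omit(par)
    leaves <- remaining[!is_parent]
    if (length(leaves) == 0) {
      if (length(remaining) > 0)
        stop("pedigree contains a cycle (an animal is its own ancestor)")
      break
    }
    remaining <- setdiff(remaining, leaves)
    if (length(remaining) == 0) break
  }
  invisible(TRUE)
}

parents_of <- function(ped, id) {
  i <- match(id, ped$id)
  stats::na.omit(c(ped$sire[i], ped$dam[i]))
}

#' Ancestors of an animal with generation distance
#'
#' Breadth-first closure over sire/dam links. An ancestor reachable by
#' several paths is listed once at its minimum generation distance.
#'
#' @param ped A [pedigree()].
#' @param id Focal animal.
#' @param max_gen Maximum generation depth (1 = parents); `Inf` = unlimited.
#' @return data.frame with `id` and `generation`.
#' @export
ancestors <- function(ped, id, max_gen = Inf) {
  if (!id %in% ped$id) stop("unknown animal id: ", id)
  seen <- character()
  gen <- integer()
  frontier <- id
  g <- 0L
  while (length(frontier) > 0 && g < max_gen) {
    g <- g + 1L
    frontier <- unique(unlist(lapply(frontier, parents_of, ped = ped)))
    frontier <- setdiff(frontier, seen)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
    gen <- c(gen, rep(g, length(frontier)))
  }
  data.frame(id = seen, generation = gen, stringsAsFactors = FALSE)
}

#' Common ancestors of two animals
#'
#' Intersection of the two ancestor closures. A non-empty result for a
#' sire/dam pair marks an inbreeding loop for their offspring (attribute
#' `inbreeding_loop`).
#'
#' @param ped A [pedigree()].
#' @param id1,id2 The two animals (e.g. the parents of a case).
#' @param max_gen Generation depth searched from each animal.
#' @return data.frame `id`, `generation1`, `generation2`, with attribute
#'   `inbreeding_loop`.
#' @export
common_ancestors <- function(ped, id1, id2, max_gen = Inf) {
  a1 <- ancestors(ped, id1, max_gen)
  a2 <- ancestors(ped, id2, max_gen)
  ids <- intersect(a1$id, a2$id)
  out <- data.frame(id = ids,
                    generation1 = a1$generation[match(ids, a1$id)],
                    generation2 = a2$generation[match(ids, a2$id)],
                    stringsAsFactors = FALSE)
  attr(out, "inbreeding_loop") <- nrow(out) > 0
  out
}

# all upward paths from `from` to each ancestor; a path is the vector of
# node ids starting at `from` and ending at the ancestor
ancestral_paths <- function(ped, from) {
  res <- list()
  walk <- function(path) {
    tip <- path[length(path)]
    res[[length(res) + 1]] <<- path
    for (p in parents_of(ped, tip)) walk(c(path, p))
  }
  walk(from)
  res
}

#' Wright's inbreeding coefficient by path counting
#'
#' F of an animal is the sum over common ancestors A of its parents and over
#' pairs of ancestor-disjoint paths (one from each parent up to A) of
#' `(1/2)^(n1 + n2 + 1) * (1 + F_A)`, with the ancestor's own F computed
#' recursively and founders at F = 0. Path pairs may share no animal other
#' than A.
#'
#' @param ped A [pedigree()].
#' @param id Focal animal.
#' @return F (0 for founders and outbred animals; 0.25 for parent-offspring
#'   or full-sib matings with outbred parents).
#' @export
wright_inbreeding <- function(ped, id) {
  memo <- new.env(parent = emptyenv())
  f_of(ped, id, memo)
}

f_of <- function(ped, id, memo) {
  if (!id %in% ped$id) stop("unknown animal id: ", id)
  if (!is.null(memo[[id]])) return(memo[[id]])
  i <- match(id, ped$id)
  s <- ped$sire[i]; d <- ped$dam[i]
  if (is.na(s) || is.na(d)) { memo[[id]] <- 0; return(0) }
  ps <- ancestral_paths(ped, s)
  pd <- ancestral_paths(ped, d)
  f <- 0
  for (a in ps) for (b in pd) {
    if (a[length(a)] != b[length(b)]) next
    anc <- a[length(a)]
    shared <- intersect(a, b)
    if (!identical(shared, anc)) next      # ancestor-disjoint pairs only
    n1 <- length(a) - 1L
    n2 <- length(b) - 1L
    f <- f + 0.5^(n1 + n2 + 1) * (1 + f_of(ped, anc, memo))
  }
  memo[[id]] <- f
  f
}

#' Additive relationship matrix (tabular method)
#'
#' The classical recursive tabular construction of the numerator
#' relationship matrix A over the whole pedigree; inbreeding coefficients
#' are `diag(A) - 1`. Kept alongside the path-counting method as an
#' algebraically independent route to the same quantity.
#'
#' @param ped A [pedigree()].
#' @return Matrix A with animal ids as dimnames.
#' @export
additive_relationship <- function(ped) {
  ids <- topological_order(ped)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  si <- match(ped$sire[match(ids, ped$id)], ids)
  di <- match(ped$dam[match(ids, ped$id)], ids)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      v <- 0
      if (!is.na(s)) v <- v + 0.5 * A[s, j]
      if (!is.na(d)) v <- v + 0.5 * A[d, j]
      A[i, j] <- A[j, i] <- v
    }
  }
  A
}

topological_order <- function(ped) {
  ids <- ped$id
  placed <- character()
  while (length(placed) < length(ids)) {
    ready <- vapply(ids, function(x) {
      if (x %in% placed) return(FALSE)
      all(parents_of(ped, x) %in% placed)
    }, logical(1))
    if (!any(ready)) stop("pedigree contains a cycle")
    placed <- c(placed, ids[ready])
  }
  placed
}

#' Trace labeled carriers toward candidate founder animals
#'
#' Given genotype labels on the pedigree, finds the ancestors common to all
#' labeled carriers (het or hom_alt) and reduces them to the minimal
#' candidates: common ancestors with no proper descendant in the common
#' set, i.e. the most recent animals from which every carrier can descend.
#' For each carrier/candidate pair, descent is genotype-consistent if at
#' least one upward path avoids confirmed hom_ref animals; carriers with no
#' consistent path to any candidate are flagged.
#'
#' @param ped A [pedigree()] with genotype labels.
#' @param max_gen Generation depth searched (default unlimited).
#' @return List with `carriers`, `common_ancestors`, `candidates` (minimal
#'   candidate founders), and `violations` (carriers with no
#'   genotype-consistent descent path to any candidate).
#' @export
trace_carriers <- function(ped, max_gen = Inf) {
  carriers <- ped$id[ped$genotype %in% c("het", "hom_alt")]
  if (length(carriers) == 0) stop("no animals labeled het or hom_alt")
  closures <- lapply(carriers, function(cid) ancestors(ped, cid, max_gen)$id)
  common <- Reduce(intersect, closures)
  if (length(carriers) == 1) common <- closures[[1]]
  if (length(common) == 0)
    return(list(carriers = carriers, common_ancestors = character(),
                candidates = character(), violations = character()))
  # minimal = no proper descendant within the common set
  minimal <- vapply(common, function(a) {
    desc_in_common <- vapply(setdiff(common, a), function(b)
      a %in% ancestors(ped, b)$id, logical(1))
    !any(desc_in_common)
  }, logical(1))
  candidates <- common[minimal]
  consistent <- function(cid, anc) {
    paths <- ancestral_paths(ped, cid)
    paths <- Filter(function(p) p[length(p)] == anc, paths)
    any(vapply(paths, function(p) {
      inner <- p[-c(1, length(p))]
      !any(ped$genotype[match(inner, ped$id)] == "hom_ref")
    }, logical(1)))
  }
  violations <- carriers[vapply(carriers, function(cid)
    !any(vapply(candidates, function(a) consistent(cid, a), logical(1))),
    logical(1))]
  list(carriers = carriers, common_ancestors = common,
       candidates = candidates, violations = violations)
}
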