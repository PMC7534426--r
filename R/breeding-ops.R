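# Mating and selection operations of the breeding phase. No mutation here:
# recurrent mutation is restricted to the historical population.

# Internal: offspring cohort from explicit 1-based parent index pairs.
# Parent ids are kept in the lineage for pedigree audits.
mateCohort <- function(cohort, mothers, fathers, ids, family = NA_character_,
                       cycle = 0L, stage = "offspring") {
  hap <- cpp_mate(cohort@haplo, mothers - 1L, fathers - 1L,
                  chromStarts(cohort@map), cohort@map@posCM,
                  cohort@map@chromLengthCM)
  n <- length(mothers)
  new("Cohort",
    haplo = hap,
    id = ids,
    lineage = data.frame(
      family = rep_len(family, n), cycle = rep_len(as.integer(cycle), n),
      stage = rep_len(stage, n),
      mother = cohort@id[mothers], father = cohort@id[fathers],
      stringsAsFactors = FALSE
    ),
    map = cohort@map
  )
}

# Internal: n distinct parent pairs drawn uniformly from `pool` (indices).
drawDistinctPairs <- function(pool, n) {
  mo <- sample(pool, n, replace = TRUE)
  fa <- sample(pool, n, replace = TRUE)
  bad <- which(fa == mo)
  while (length(bad) > 0) {
    fa[bad] <- sample(pool, length(bad), replace = TRUE)
    bad <- bad[fa[bad] == mo[bad]]
  }
  list(mo = mo, fa = fa)
}

#' One meiosis
#'
#' Samples a single gamete from one individual: per chromosome the number
#' of crossovers is Poisson(lambda = 1), crossover locations are uniform on
#' the map (no interference), and the starting chromatid is a fair coin.
#'
#' @param cohort a [Cohort-class].
#' @param individual index or id of the parent.
#' @return Integer vector of gamete alleles (0/1), one per locus.
#' @export
meiosis <- function(cohort, individual = 1L) {
  stopifnot(is(cohort, "Cohort"))
  if (is.character(individual)) individual <- match(individual, cohort@id)
  if (is.na(individual) || individual < 1L || individual > nInd(cohort))
    stop("unknown individual")
  as.integer(cpp_gamete(cohort@haplo, as.integer(individual) - 1L,
                        chromStarts(cohort@map), cohort@map@posCM,
                        cohort@map@chromLengthCM))
}

#' Cross two plants
#'
#' Pair cross of two distinct plants: each offspring unites one meiosis
#' from each parent. Selfing is rejected (gametophytic self-incompatibility).
#'
#' @param cohort a [Cohort-class] containing both parents.
#' @param mother,father indices or ids of the two parents; must differ.
#' @param nOffspring family size.
#' @param family,cycle,stage lineage labels for the offspring.
#' @return A [Cohort-class] of full sibs.
#' @export
cross <- function(cohort, mother, father, nOffspring = 40L,
                  family = NA_character_, cycle = 0L, stage = "F1") {
  stopifnot(is(cohort, "Cohort"))
  if (is.character(mother)) mother <- match(mother, cohort@id)
  if (is.character(father)) father <- match(father, cohort@id)
  if (anyNA(c(mother, father))) stop("unknown parent")
  if (mother == father)
    stop("selfing is not allowed (self-incompatibility)")
  n <- as.integer(nOffspring)
  mateCohort(cohort, rep.int(as.integer(mother), n),
             rep.int(as.integer(father), n),
             ids = sprintf("%s_%d", if (is.na(family)) "X" else family,
                           seq_len(n)),
             family = family, cycle = cycle, stage = stage)
}

#' Create F1 families from varieties
#'
#' For each family a random pair of distinct varieties is drawn and one
#' random plant taken from each; the two plants are pair-crossed into a
#' full-sib F1 family. Defaults give 250 families of 40 (10,000 plants),
#' i.e., on average 25 parents per initial variety.
#'
#' @param varieties list of variety [Cohort-class] objects.
#' @param nFamilies number of F1 families.
#' @param familySize plants per family.
#' @param cycle breeding-cycle label for the offspring.
#' @return A single [Cohort-class]; `lineage(x)$family` identifies the
#'   families (`"C<cycle>F<fam>"`).
#' @export
makeF1Families <- function(varieties, nFamilies = 250L, familySize = 40L,
                           cycle = 1L) {
  if (length(varieties) < 2L) stop("at least 2 source varieties required")
  pool <- combineCohorts(varieties)
  grp <- pool@lineage$family
  nFamilies <- as.integer(nFamilies)
  vPair <- t(vapply(seq_len(nFamilies), function(i)
    sample(unique(grp), 2L), character(2)))
  mo <- vapply(vPair[, 1], function(v) sample(which(grp == v), 1L), integer(1))
  fa <- vapply(vPair[, 2], function(v) sample(which(grp == v), 1L), integer(1))
  makeFamiliesFromParents(pool, mo, fa, familySize, cycle, stage = "F1")
}

# Internal: F1 families from explicit parent index pairs in a parent pool.
makeFamiliesFromParents <- function(pool, mo, fa, familySize, cycle,
                                    stage = "F1") {
  nFamilies <- length(mo)
  familySize <- as.integer(familySize)
  moAll <- rep(mo, each = familySize)
  faAll <- rep(fa, each = familySize)
  famLab <- sprintf("C%dF%d", cycle, rep(seq_len(nFamilies),
                                         each = familySize))
  mateCohort(pool, moAll, faAll,
             ids = sprintf("%s_%d", famLab,
                           rep(seq_len(familySize), nFamilies)),
             family = famLab, cycle = cycle, stage = stage)
}

#' Random mating within a family
#'
#' Offspring from uniformly drawn distinct parent pairs within one family
#' (no selfing). Used for F1 to F2 and SYN1 to SYN2 steps.
#'
#' @param family a [Cohort-class] with at least 2 members.
#' @param nOffspring number of offspring.
#' @param stage lineage stage label for the offspring.
#' @return A [Cohort-class] of offspring carrying the family's label.
#' @export
intermateFamily <- function(family, nOffspring = 40L, stage = "F2") {
  stopifnot(is(family, "Cohort"))
  n <- nInd(family)
  if (n < 2L) stop("cannot intermate a family of fewer than 2 plants")
  nOffspring <- as.integer(nOffspring)
  pr <- drawDistinctPairs(seq_len(n), nOffspring)
  fam <- family@lineage$family[1]
  mateCohort(family, pr$mo, pr$fa,
             ids = sprintf("%s_%s%d", ifelse(is.na(fam), "X", fam), stage,
                           seq_len(nOffspring)),
             family = fam, cycle = family@lineage$cycle[1], stage = stage)
}

#' Polycross an 8-parent group
#'
#' Random intermating among a small group of distinct selected plants
#' (default 8) founding a synthetic variety: offspring come from uniformly
#' drawn distinct parent pairs within the group, no selfing.
#'
#' @param parents a [Cohort-class] of exactly `groupSize` distinct plants.
#' @param nOffspring number of SYN1 offspring.
#' @param groupSize required number of parents (default 8).
#' @param group synthetic-group label for the offspring.
#' @return A [Cohort-class], stage `"SYN1"`.
#' @export
polycross <- function(parents, nOffspring = 40L, groupSize = 8L,
                      group = NA_character_) {
  stopifnot(is(parents, "Cohort"))
  if (nInd(parents) != groupSize)
    stop("polycross requires exactly ", groupSize, " parents")
  if (anyDuplicated(parents@id)) stop("duplicate parents in polycross")
  pr <- drawDistinctPairs(seq_len(groupSize), as.integer(nOffspring))
  mateCohort(parents, pr$mo, pr$fa,
             ids = sprintf("%s_SYN1_%d", ifelse(is.na(group), "G", group),
                           seq_len(as.integer(nOffspring))),
             family = group, cycle = parents@lineage$cycle[1], stage = "SYN1")
}

#' Multi-trait selection index
#'
#' Weighted sum of per-trait values (plot mean phenotypes for phenotypic
#' selection, GEBVs for genomic selection) over the index traits. With
#' `standardize = TRUE` each trait is z-scored within the candidate cohort
#' first, operationalizing equal emphasis on each trait; the default
#' weights are 1/3 each for traits 1, 3 and 4.
#'
#' @param values candidates x traits matrix of phenotypes or GEBVs.
#' @param traits columns entering the index (default `c(1, 3, 4)` when
#'   `values` has 4 columns, else all columns).
#' @param weights index weights, one per index trait, summing to 1.
#' @param standardize z-score each index trait within the candidates.
#' @return Numeric index score per candidate.
#' @export
selectionIndex <- function(values, traits = NULL, weights = NULL,
                           standardize = TRUE) {
  values <- as.matrix(values)
  if (is.null(traits))
    traits <- if (ncol(values) >= 4) c(1L, 3L, 4L) else seq_len(ncol(values))
  v <- values[, traits, drop = FALSE]
  if (is.null(weights)) weights <- rep(1 / length(traits), length(traits))
  if (length(weights) != length(traits))
    stop("one weight per index trait required")
  if (abs(sum(weights) - 1) > 1e-8) stop("index weights must sum to 1")
  if (standardize) {
    s <- apply(v, 2, sd)
    s[s == 0] <- 1
    v <- sweep(sweep(v, 2, colMeans(v)), 2, s, "/")
  }
  drop(v %*% weights)
}

#' @rdname selectionIndex
#' @param phenotypes candidates x traits matrix of plot mean phenotypes.
#' @export
phenotypicIndex <- function(phenotypes, traits = NULL, weights = NULL,
                            standardize = TRUE) {
  selectionIndex(phenotypes, traits, weights, standardize)
}

#' @rdname selectionIndex
#' @param gebvs candidates x traits matrix of GEBVs.
#' @export
gebvIndex <- function(gebvs, traits = NULL, weights = NULL,
                      standardize = TRUE) {
  selectionIndex(gebvs, traits, weights, standardize)
}

#' Truncation selection
#'
#' Indices of the `n` highest-scoring candidates; ties are broken by
#' candidate id (or position) so selection is deterministic.
#'
#' @param scores numeric scores.
#' @param n number to select.
#' @param ids optional ids used for tie-breaking (default positions).
#' @return Integer indices of the selected candidates, best first.
#' @export
selectTop <- function(scores, n, ids = NULL) {
  n <- as.integer(n)
  if (n > length(scores)) stop("cannot select more candidates than exist")
  if (is.null(ids)) ids <- seq_along(scores)
  ord <- order(-scores, ids)
  ord[seq_len(n)]
}

#' Group polycross parents by heading date
#'
#' Sorts the selected single plants by their heading-date (trait 2)
#' phenotype and partitions them into consecutive groups of `groupSize`, so
#' each synthetic is founded by plants of similar maturity; group terciles
#' correspond to early / intermediate / late classes. Ties are broken by
#' id, making the partition deterministic.
#'
#' @param hd heading-date phenotypes, one per plant.
#' @param groupSize plants per group (default 8).
#' @param ids optional plant ids for tie-breaking.
#' @return List with `groups` (list of integer index vectors, one per
#'   group, ordered early to late) and `category` (`"early"`,
#'   `"intermediate"` or `"late"` per group).
#' @export
groupByHeading <- function(hd, groupSize = 8L, ids = NULL) {
  n <- length(hd)
  groupSize <- as.integer(groupSize)
  if (n %% groupSize != 0L)
    stop("number of plants (", n, ") not divisible by group size (",
         groupSize, ")")
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(hd, ids)
  nGroups <- n %/% groupSize
  groups <- split(ord, rep(seq_len(nGroups), each = groupSize))
  names(groups) <- NULL
  category <- cut(seq_len(nGroups), 3,
                  labels = c("early", "intermediate", "late"))
  list(groups = groups, category = as.character(category))
}
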