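## Somatic hypermutation at cell division: Poisson mutation count, fate-tree
## routing (region -> type -> effect), type-consistent nucleotide editing,
## and the global sequence-affinity registry.

#' Construct an SHM fate tree
#'
#' @param regionProb named numeric over the seven regions, summing to 1.
#' @param replacementProb named numeric, P(replacement | region).
#' @param effectProb 7 x 3 matrix (`affinity`, `lethal`, `neutral`),
#'   P(effect | region, replacement); FWR rows must put 0 on `affinity`.
#' @return a [FateTree-class].
#' @export
fateTree <- function(regionProb, replacementProb, effectProb) {
  new("FateTree", regionProb = regionProb,
      replacementProb = replacementProb, effectProb = effectProb)
}

#' Default SHM fate tree
#'
#' CDR region probabilities 0.10/0.03/0.19 with per-CDR replacement
#' probabilities 0.79/0.76/0.75 and every CDR replacement affinity-changing,
#' so the per-mutation affinity-change probability is
#' 0.10*0.79 + 0.03*0.76 + 0.19*0.75 = 0.2443. Framework regions carry the
#' remaining region mass (roughly length-proportional); FWR replacements are
#' lethal (nonsense) or neutral with equal probability and never change
#' affinity. All values are configuration, not constants.
#'
#' @return a [FateTree-class].
#' @examples
#' affinityChangeProbability(defaultFateTree())  # 0.2443
#' @export
defaultFateTree <- function() {
  regionProb <- c(FWR1 = 0.25, CDR1 = 0.10, FWR2 = 0.14, CDR2 = 0.03,
                  FWR3 = 0.25, CDR3 = 0.19, FWR4 = 0.04)
  replacementProb <- c(FWR1 = 0.75, CDR1 = 0.79, FWR2 = 0.75, CDR2 = 0.76,
                       FWR3 = 0.75, CDR3 = 0.75, FWR4 = 0.75)
  effectProb <- rbind(
    FWR1 = c(0, 0.5, 0.5),
    CDR1 = c(1, 0, 0),
    FWR2 = c(0, 0.5, 0.5),
    CDR2 = c(1, 0, 0),
    FWR3 = c(0, 0.5, 0.5),
    CDR3 = c(1, 0, 0),
    FWR4 = c(0, 0.5, 0.5))
  colnames(effectProb) <- EFFECT_LEVELS
  fateTree(regionProb, replacementProb, effectProb)
}

#' Per-mutation probability of an affinity-changing outcome
#'
#' Sum over regions of P(region) * P(replacement | region) *
#' P(affinity-changing | region, replacement). With the default tree this is
#' 0.2443.
#'
#' @param tree a [FateTree-class].
#' @return probability in `[0, 1]`.
#' @export
affinityChangeProbability <- function(tree) {
  sum(tree@regionProb * tree@replacementProb * tree@effectProb[, "affinity"])
}

#' Sample the number of somatic hypermutations at one division
#'
#' Untruncated Poisson with rate `lambda` = 0.4 by default: a per-base
#' mutation rate of 1e-3 per division over a ~400 nt heavy chain, giving one
#' or more mutations in ~33% of divisions.
#'
#' @param lambda Poisson rate, > 0.
#' @param rng optional [newRngStream()] stream.
#' @return non-negative integer count.
#' @export
sampleMutationCount <- function(lambda = 0.4, rng = NULL) {
  stopifnot(lambda > 0)
  if (is.null(rng)) rpois(1L, lambda) else withStream(rng, rpois(1L, lambda))
}

#' Sample a mutation fate from the tree
#'
#' Sequential categorical sampling: region, then type (replacement/silent),
#' then, for replacements, the effect. Silent mutations have effect
#' `"none"`.
#'
#' @param tree a [FateTree-class].
#' @param rng optional [newRngStream()] stream.
#' @return list with `region`, `type`, `effect`.
#' @export
sampleFate <- function(tree, rng = NULL) {
  draw <- function() {
    region <- sample(REGION_LEVELS, 1L, prob = tree@regionProb)
    repl <- runif(1L) < tree@replacementProb[[region]]
    if (repl) {
      effect <- sample(EFFECT_LEVELS, 1L, prob = tree@effectProb[region, ])
      list(region = region, type = "replacement", effect = effect)
    } else {
      list(region = region, type = "silent", effect = "none")
    }
  }
  if (is.null(rng)) draw() else withStream(rng, draw())
}

#' Apply one type-consistent nucleotide substitution in a region
#'
#' Substitutes exactly one nucleotide inside the drawn region so that the
#' codon-level consequence matches the requested mutation type: `"silent"`
#' leaves the amino acid unchanged; `"replacement"` changes it (to a stop
#' codon when `lethal = TRUE`, and never to a stop otherwise). The retry
#' protocol tries the three alternative nucleotides at a uniformly drawn
#' position in random order and, if none matches, moves to a fresh position;
#' it fails only after exhausting every (position, nucleotide) pair in the
#' region. Positions and nucleotides are uniform: no mutation hot/cold
#' spots.
#'
#' @param sequence nucleotide string.
#' @param regions 7-row region annotation `data.frame` (`region`, `start`,
#'   `end`; 0-based half-open).
#' @param frame reading-frame offset.
#' @param region region name to mutate in.
#' @param type `"replacement"` or `"silent"`.
#' @param lethal for replacements, whether the substitution must create an
#'   in-frame stop codon.
#' @param rng optional [newRngStream()] stream.
#' @return list with `sequence` (edited), `position` (0-based), `old`,
#'   `new` nucleotides.
#' @export
mutateSequence <- function(sequence, regions, frame, region,
                           type = c("replacement", "silent"),
                           lethal = FALSE, rng = NULL) {
  type <- match.arg(type)
  if (lethal && type != "replacement")
    stop("lethal outcomes require a replacement mutation")
  row <- regions[regions$region == region, , drop = FALSE]
  if (nrow(row) != 1L || row$end <= row$start)
    stop("region ", region, " is missing or empty")
  doDraw <- function() {
    candidates <- seq.int(row$start, row$end - 1L)
    # restrict to positions inside complete codons
    len <- nchar(sequence)
    codonStart <- frame + 3L * ((candidates - frame) %/% 3L)
    candidates <- candidates[candidates >= frame & codonStart + 3L <= len]
    if (length(candidates) == 0L)
      stop("region ", region, " has no positions in complete codons")
    remaining <- sample(candidates)       # random order = uniform fresh picks
    nts <- c("A", "C", "G", "T")
    for (pos in remaining) {
      oldNt <- substr(sequence, pos + 1L, pos + 1L)
      for (nt in sample(setdiff(nts, oldNt))) {
        tw <- translateCodonWindow(sequence, frame, pos, nt)
        cls <- if (tw$aaNew == tw$aa) "silent"
               else if (tw$aaNew == "*") "lethal"
               else "replacement"
        want <- if (type == "silent") "silent"
                else if (lethal) "lethal" else "replacement"
        if (cls == want) {
          edited <- sequence
          substr(edited, pos + 1L, pos + 1L) <- nt
          return(list(sequence = edited, position = pos, old = oldNt,
                      new = nt))
        }
      }
    }
    stop("no ", if (lethal) "lethal " else "", type,
         " substitution is possible anywhere in region ", region)
  }
  if (is.null(rng)) doDraw() else withStream(rng, doDraw())
}

#' Sequence-affinity registry
#'
#' Hash map from exact BcR nucleotide sequence to its shape-space position
#' and affinity, guaranteeing that affinity is a function of sequence for
#' the whole run: a sequence reached twice (by any mutation path) always
#' carries the affinity registered first. Registering an existing sequence
#' with a different affinity is an invariant breach and fails hard.
#'
#' @return `newSequenceRegistry()` returns an empty registry.
#' @export
newSequenceRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "SequenceRegistry"
  reg
}

#' @rdname newSequenceRegistry
#' @param registry a registry.
#' @param sequence exact nucleotide sequence (the key).
#' @export
registryLookup <- function(registry, sequence) {
  get0(sequence, envir = registry, inherits = FALSE)
}

#' @rdname newSequenceRegistry
#' @param position shape-space coordinates to store.
#' @param affinity affinity to store.
#' @return `registryRegister()` returns the authoritative
#'   (position, affinity) record: the pre-existing one if the sequence was
#'   already registered (first registration wins).
#' @export
registryRegister <- function(registry, sequence, position, affinity) {
  hit <- registryLookup(registry, sequence)
  if (!is.null(hit)) {
    if (abs(hit$affinity - affinity) > 1e-9)
      stop("sequence-affinity registry conflict: sequence already ",
           "registered with affinity ", hit$affinity, ", got ", affinity)
    return(hit)
  }
  rec <- list(position = position, affinity = affinity)
  assign(sequence, rec, envir = registry)
  rec
}

#' @rdname newSequenceRegistry
#' @export
registrySize <- function(registry) length(ls(registry, all.names = TRUE))

#' @rdname newSequenceRegistry
#' @return `registrySnapshot()` returns a `data.frame` (`sequence`,
#'   `affinity`).
#' @export
registrySnapshot <- function(registry) {
  keys <- ls(registry, all.names = TRUE)
  data.frame(
    sequence = keys,
    affinity = vapply(keys, function(k) registry[[k]]$affinity, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply somatic hypermutation to a dividing cell's BcR
#'
#' Samples `m ~ Poisson(lambda)` mutations and routes each independently
#' through the fate tree. Affinity-changing mutations (CDR replacements)
#' move the BcR one step in shape space and recompute the Gaussian affinity;
#' silent and neutral mutations edit the nucleotide sequence but leave the
#' shape position untouched; a lethal (nonsense) mutation sets affinity to
#' zero, flags dark-zone apoptosis, and stops further processing. Every
#' sequence reached is reconciled with the registry, so a cell re-deriving
#' an already-seen sequence inherits its registered position and affinity.
#'
#' @param sequence current BcR nucleotide sequence.
#' @param regions 7-row region annotation of the sequence.
#' @param frame reading-frame offset.
#' @param position current shape-space coordinates.
#' @param affinity current affinity.
#' @param tree a [FateTree-class].
#' @param registry a [newSequenceRegistry()] registry.
#' @param shapeCfg a [shapeSpaceConfig()].
#' @param lambda Poisson mutation rate per division.
#' @param rng optional [newRngStream()] stream.
#' @return list with `sequence`, `position`, `affinity`, `apoptosis`,
#'   `m`, and `outcomes` (a `data.frame` of per-mutation records).
#' @export
applySHM <- function(sequence, regions, frame, position, affinity, tree,
                     registry, shapeCfg, lambda = 0.4, rng = NULL) {
  m <- sampleMutationCount(lambda, rng)
  outcomes <- vector("list", m)
  apoptosis <- FALSE
  if (m > 0L) {
    for (k in seq_len(m)) {
      fate <- sampleFate(tree, rng)
      lethal <- identical(fate$effect, "lethal")
      ## a short region may offer no substitution of the drawn type (e.g. no
      ## stop-creating edit); degrade lethal -> plain replacement -> silent,
      ## dropping the mutation if the region admits no edit of any type
      mut <- tryCatch(
        mutateSequence(sequence, regions, frame, fate$region,
                       type = fate$type, lethal = lethal, rng = rng),
        error = function(e) NULL)
      if (is.null(mut) && lethal) {
        lethal <- FALSE
        fate$effect <- "neutral"
        mut <- tryCatch(
          mutateSequence(sequence, regions, frame, fate$region,
                         type = "replacement", rng = rng),
          error = function(e) NULL)
      }
      if (is.null(mut) && fate$type == "replacement") {
        fate$type <- "silent"; fate$effect <- "none"
        mut <- tryCatch(
          mutateSequence(sequence, regions, frame, fate$region,
                         type = "silent", rng = rng),
          error = function(e) NULL)
      }
      if (is.null(mut)) next
      sequence <- mut$sequence
      if (lethal) {
        affinity <- 0
        apoptosis <- TRUE
        registryRegister(registry, sequence, position, 0)
      } else {
        hit <- registryLookup(registry, sequence)
        if (!is.null(hit)) {
          position <- hit$position
          affinity <- hit$affinity
        } else {
          if (identical(fate$effect, "affinity")) {
            position <- mutatePosition(position, shapeCfg, rng)
            affinity <- affinityFromDistance(
              l1Distance(position, shapeCfg$antigen), shapeCfg$gamma)
          }
          registryRegister(registry, sequence, position, affinity)
        }
      }
      outcomes[[k]] <- data.frame(
        region = fate$region, type = fate$type, effect = fate$effect,
        position = mut$position, old = mut$old, new = mut$new,
        affinity = affinity, stringsAsFactors = FALSE)
      if (apoptosis) break
    }
  }
  outcomes <- outcomes[!vapply(outcomes, is.null, logical(1))]
  list(sequence = sequence, position = position, affinity = affinity,
       apoptosis = apoptosis, m = m,
       outcomes = if (length(outcomes)) do.call(rbind, outcomes) else
         data.frame(region = character(), type = character(),
                    effect = character(), position = integer(),
                    old = character(), new = character(),
                    affinity = numeric(), stringsAsFactors = FALSE))
}
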