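#' Build the binary presence/absence character matrix of one case
#'
#' One character per distinct `(chrom, pos, ref, alt)` somatic variant;
#' presence means the variant passed filtering in that sample. The
#' myometrium reference `Nm` is included as the all-absent outgroup row
#' (germline subtraction guarantees it carries none of the characters).
#' Duplicate keys within a sample collapse to one character.
#'
#' @param somaticTable filtered somatic variant data.frame of one case.
#' @param taxa sample roles to include; defaults to `Nm` plus every
#'   lesion role present in the table.
#' @return a [BinaryCharacterMatrix-class].
#' @export
buildCharacterMatrix <- function(somaticTable, taxa = NULL) {
  if (nrow(somaticTable) && length(unique(somaticTable$case_id)) > 1L)
    stop("character matrix must be built per case", call. = FALSE)
  roles <- intersect(SAMPLE_ROLES, unique(somaticTable$role))
  if (is.null(taxa)) taxa <- union("Nm", roles)
  taxa <- intersect(SAMPLE_ROLES, taxa)  # canonical order
  keys <- unique(.variantKey(somaticTable))
  mat <- matrix(0L, nrow = length(taxa), ncol = length(keys),
                dimnames = list(taxa, keys))
  if (length(keys)) {
    for (r in setdiff(taxa, "Nm")) {
      sub <- somaticTable[somaticTable$role == r, , drop = FALSE]
      mat[r, unique(.variantKey(sub))] <- 1L
    }
  }
  informative <- if (length(keys)) {
    cs <- colSums(mat)
    cs > 0L & cs < nrow(mat)
  } else logical(0)
  new("BinaryCharacterMatrix", taxa = taxa, mat = mat,
      characterIds = keys, informative = informative)
}

## ---- exhaustive unrooted topology enumeration ----------------------

# topologies are edge matrices over node ids; tips are 1..n (order of
# `taxa`), internal nodes n+1, n+2, ...
.allUnrootedTopologies <- function(n) {
  if (n < 3L || n > 6L)
    stop("exhaustive search supports 3 to 6 taxa", call. = FALSE)
  base <- list(list(edges = rbind(c(n + 1L, 1L), c(n + 1L, 2L),
                                  c(n + 1L, 3L)),
                    nextNode = n + 2L))
  trees <- base
  for (t in seq_len(n)[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(e) {
        x <- tr$nextNode
        a <- tr$edges[e, 1L]; b <- tr$edges[e, 2L]
        list(edges = rbind(tr$edges[-e, , drop = FALSE],
                           c(a, x), c(x, b), c(x, t)),
             nextNode = x + 1L)
      })
    }), recursive = FALSE)
  }
  lapply(trees, `[[`, "edges")
}

# root an unrooted binary topology on the edge incident to tip `rootTip`;
# returns children list indexed by node id and a postorder node sequence
.rootTopology <- function(edges, rootTip) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(if (a <= length(adj)) adj[[a]], b)
    adj[[b]] <- c(if (b <= length(adj)) adj[[b]], a)
  }
  anchor <- adj[[rootTip]][1L]
  maxNode <- max(edges)
  children <- vector("list", maxNode + 1L)
  rootId <- maxNode + 1L
  children[[rootId]] <- c(rootTip, anchor)
  # orient away from the root by BFS
  queue <- list(c(anchor, rootTip))
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    node <- cur[1L]; parent <- cur[2L]
    kids <- setdiff(adj[[node]], parent)
    children[[node]] <- kids
    for (k in kids) if (k > length(adj) || length(adj[[k]]) > 1L)
      queue <- c(queue, list(c(k, node)))
    for (k in kids) if (k <= length(adj) && length(adj[[k]]) > 1L) {}
  }
  # postorder over the rooted tree
  post <- integer(0)
  stack <- rootId
  visited <- integer(0)
  rec <- function(node) {
    for (k in children[[node]]) if (!is.null(children[[k]]) &&
                                    length(children[[k]])) rec(k)
    post <<- c(post, node)
  }
  rec(rootId)
  list(children = children, rootId = rootId, postorder = post)
}

# vectorized Fitch downpass over all characters; states 0/1 encoded as
# bitmasks 1/2. Returns per-character minimum changes and the downpass
# sets for the uppass.
.fitchDown <- function(rooted, statesMat) {
  nChar <- ncol(statesMat)
  maxNode <- length(rooted$children)
  sets <- matrix(0L, nrow = maxNode, ncol = nChar)
  changes <- integer(nChar)
  nTaxa <- nrow(statesMat)
  for (tip in seq_len(nTaxa))
    sets[tip, ] <- bitwShiftL(1L, statesMat[tip, ])
  for (node in rooted$postorder) {
    kids <- rooted$children[[node]]
    s <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- bitwAnd(s, sets[k, ])
      uni <- bitwOr(s, sets[k, ])
      miss <- inter == 0L
      changes <- changes + miss
      s <- ifelse(miss, uni, inter)
    }
    sets[node, ] <- s
  }
  list(score = changes, sets = sets)
}

# uppass assigning one minimal state per node (parent state kept when
# admissible, so changes fall on the most terminal admissible branch)
# and counting changes per oriented edge
.fitchBranchChanges <- function(rooted, down, statesMat) {
  nChar <- ncol(statesMat)
  maxNode <- length(rooted$children)
  state <- matrix(NA_integer_, nrow = maxNode, ncol = nChar)
  rootSet <- down$sets[rooted$rootId, ]
  # prefer the outgroup (first root child, the root tip) state
  tipState <- statesMat[rooted$children[[rooted$rootId]][1L], ]
  tipMask <- bitwShiftL(1L, tipState)
  rootState <- ifelse(bitwAnd(rootSet, tipMask) > 0L, tipState,
                      ifelse(bitwAnd(rootSet, 1L) > 0L, 0L, 1L))
  state[rooted$rootId, ] <- rootState
  edgeChanges <- list()
  pre <- rev(rooted$postorder)
  # root first, then internal nodes top-down; tips handled inline
  assign_children <- function(node) {
    for (k in rooted$children[[node]]) {
      kset <- down$sets[k, ]
      pstate <- state[node, ]
      pmask <- bitwShiftL(1L, pstate)
      keep <- bitwAnd(kset, pmask) > 0L
      kstate <- ifelse(keep, pstate, ifelse(bitwAnd(kset, 1L) > 0L, 0L, 1L))
      state[k, ] <<- kstate
      edgeChanges[[paste(node, k)]] <<- sum(kstate != pstate)
    }
  }
  for (node in pre) assign_children(node)
  list(state = state, edgeChanges = edgeChanges)
}

# tips below each node in the rooted orientation
.tipsBelow <- function(rooted, nTaxa) {
  below <- vector("list", length(rooted$children))
  for (tip in seq_len(nTaxa)) below[[tip]] <- tip
  for (node in rooted$postorder) {
    below[[node]] <- sort(unlist(lapply(rooted$children[[node]],
                                        function(k) below[[k]])))
  }
  below
}

# the non-trivial splits of an unrooted topology, as canonical strings
.topologySplits <- function(edges, taxa) {
  n <- length(taxa)
  rooted <- .rootTopology(edges, 1L)
  below <- .tipsBelow(rooted, n)
  internal <- setdiff(seq_along(rooted$children)[
    vapply(rooted$children, length, integer(1)) > 0], rooted$rootId)
  splits <- character(0)
  for (node in internal) {
    tips <- below[[node]]
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      side <- taxa[tips]
      other <- taxa[setdiff(seq_len(n), tips)]
      a <- paste(sort(side), collapse = "+")
      b <- paste(sort(other), collapse = "+")
      splits <- c(splits, paste(sort(c(a, b))[1L], sort(c(a, b))[2L],
                                sep = "|"))
    }
  }
  sort(unique(splits))
}

.newickFromRooted <- function(rooted, taxa, branchLen) {
  build <- function(node) {
    kids <- rooted$children[[node]]
    if (is.null(kids) || !length(kids)) {
      lab <- taxa[node]
    } else {
      lab <- paste0("(", paste(vapply(kids, build, character(1)),
                               collapse = ","), ")")
    }
    if (node == rooted$rootId) return(paste0(lab, ";"))
    len <- branchLen[[paste("parent", node)]]
    paste0(lab, ":", if (is.null(len)) 0 else len)
  }
  build(rooted$rootId)
}

#' Exhaustive maximum-parsimony tree search
#'
#' Enumerates every unrooted binary topology over the taxa (3 for 4
#' taxa, 15 for 5, 105 for 6), scores each with the Fitch small-parsimony
#' algorithm applied to every character, and returns a minimum-score
#' tree. Equally parsimonious topologies are recorded as a tie (the
#' topology classification then reports `UNRESOLVED`). Per-branch
#' character counts place each character's changes on the most terminal
#' admissible branch of a minimal reconstruction; the tree is rooted at
#' the outgroup `Nm` for display.
#'
#' @param bcm a [BinaryCharacterMatrix-class] with 3 to 6 taxa.
#' @return a [LesionTree-class].
#' @examples
#' m <- matrix(c(0L,0L,1L,1L, 0L,0L,1L,1L, 0L,1L,0L,0L), nrow = 4,
#'             dimnames = list(c("Nm","N","L","G"), NULL))
#' bcm <- new("BinaryCharacterMatrix", taxa = rownames(m), mat = m,
#'            characterIds = as.character(1:3),
#'            informative = c(TRUE, TRUE, TRUE))
#' parsimonyTree(bcm)
#' @export
parsimonyTree <- function(bcm) {
  stopifnot(is(bcm, "BinaryCharacterMatrix"))
  taxa <- bcm@taxa
  n <- length(taxa)
  if (n > 6L) stop("exhaustive search supports at most 6 taxa",
                   call. = FALSE)
  if (n < 3L) stop("at least 3 taxa are required", call. = FALSE)
  if (ncol(bcm@mat) == 0L) {
    return(new("LesionTree", tree = list(), taxa = taxa, score = 0,
               branchCounts = numeric(0), nTied = 0L,
               tiedSplits = character(0), nCharacters = 0L))
  }
  topos <- .allUnrootedTopologies(n)
  rootTip <- match("Nm", taxa)
  if (is.na(rootTip)) rootTip <- 1L
  scores <- numeric(length(topos))
  rootedList <- vector("list", length(topos))
  downList <- vector("list", length(topos))
  for (i in seq_along(topos)) {
    rooted <- .rootTopology(topos[[i]], rootTip)
    down <- .fitchDown(rooted, bcm@mat)
    scores[i] <- sum(down$score)
    rootedList[[i]] <- rooted
    downList[[i]] <- down
  }
  minScore <- min(scores)
  winners <- which(scores == minScore)
  best <- winners[1L]
  rooted <- rootedList[[best]]
  down <- downList[[best]]
  up <- .fitchBranchChanges(rooted, down, bcm@mat)
  below <- .tipsBelow(rooted, n)
  counts <- numeric(0)
  branchLen <- list()
  for (key in names(up$edgeChanges)) {
    k <- as.integer(strsplit(key, " ")[[1L]][2L])
    lab <- paste(taxa[below[[k]]], collapse = "+")
    counts[lab] <- up$edgeChanges[[key]]
    branchLen[[paste("parent", k)]] <- up$edgeChanges[[key]]
  }
  nwk <- .newickFromRooted(rooted, taxa, branchLen)
  phy <- ape::read.tree(text = nwk)
  tied <- vapply(winners, function(i)
    paste(.topologySplits(topos[[i]], taxa), collapse = ";"),
    character(1))
  new("LesionTree", tree = phy, taxa = taxa, score = minScore,
      branchCounts = counts, nTied = length(winners),
      tiedSplits = tied, nCharacters = ncol(bcm@mat))
}

#' Classify the lesion topology of a case
#'
#' `TYPE1` when the precursor and carcinoma (`L`, `G`) form a cherry
#' against the normal samples; `TYPE2` for an `N`+`L` cherry; `TYPE3`
#' for `N`+`G`. Cases whose minimum-parsimony topology is tied, that
#' lack any of `N`, `L`, `G` (e.g. no normal-gland sample), or whose
#' characters carry no grouping signal are `UNRESOLVED`.
#'
#' @param tree a [LesionTree-class] from [parsimonyTree()] or
#'   [cnaEventTree()].
#' @return one of "TYPE1", "TYPE2", "TYPE3", "UNRESOLVED".
#' @export
classifyTopology <- function(tree) {
  stopifnot(is(tree, "LesionTree"))
  if (tree@nCharacters == 0L || tree@nTied != 1L) return("UNRESOLVED")
  if (!all(c("Nm", "N", "L", "G") %in% tree@taxa)) return("UNRESOLVED")
  splits <- strsplit(tree@tiedSplits[1L], ";", fixed = TRUE)[[1L]]
  sides <- unlist(strsplit(splits, "|", fixed = TRUE))
  has <- function(pair) any(sides == paste(sort(pair), collapse = "+"))
  if (has(c("L", "G"))) return("TYPE1")
  if (has(c("N", "L"))) return("TYPE2")
  if (has(c("N", "G"))) return("TYPE3")
  "UNRESOLVED"
}

#' Parsimony tree over copy-number event characters
#'
#' Characters are the union of called event intervals per event type
#' (merged across samples); a sample shows a character when it carries
#' an overlapping event of that type. The same exhaustive Fitch
#' machinery as [parsimonyTree()] is applied, with `Nm` as the
#' all-absent outgroup.
#'
#' @param eventTable events of one case from [callCnaEvents()].
#' @param sampleRoles named character vector mapping `sample_id` to role
#'   (`N`, `L`, `G`).
#' @return a [LesionTree-class].
#' @export
cnaEventTree <- function(eventTable, sampleRoles) {
  if (nrow(eventTable) && length(unique(eventTable$case_id)) > 1L)
    stop("event tree must be built per case", call. = FALSE)
  roles <- unname(sampleRoles[unique(eventTable$sample_id)])
  taxa <- intersect(SAMPLE_ROLES, union("Nm", c(roles, "N", "L", "G")))
  if (!nrow(eventTable)) {
    return(new("LesionTree", tree = list(), taxa = taxa, score = 0,
               branchCounts = numeric(0), nTied = 0L,
               tiedSplits = character(0), nCharacters = 0L))
  }
  chars <- list()
  for (type in unique(eventTable$event_type)) {
    ev <- eventTable[eventTable$event_type == type, , drop = FALSE]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ev$chrom, IRanges::IRanges(ev$start, ev$end)))
    for (i in seq_along(gr)) {
      id <- sprintf("%s:%s:%d-%d", type,
                    as.character(GenomicRanges::seqnames(gr))[i],
                    GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
      pres <- stats::setNames(integer(length(taxa)), taxa)
      for (s in unique(ev$sample_id)) {
        evs <- ev[ev$sample_id == s, , drop = FALSE]
        hit <- any(evs$chrom == as.character(GenomicRanges::seqnames(gr))[i] &
                     evs$start <= GenomicRanges::end(gr)[i] &
                     evs$end >= GenomicRanges::start(gr)[i])
        if (hit) pres[sampleRoles[[s]]] <- 1L
      }
      chars[[id]] <- pres
    }
  }
  mat <- do.call(cbind, chars)
  rownames(mat) <- taxa
  cs <- colSums(mat)
  bcm <- new("BinaryCharacterMatrix", taxa = taxa, mat = mat,
             characterIds = colnames(mat),
             informative = cs > 0L & cs < nrow(mat))
  parsimonyTree(bcm)
}

#' Compare shared-variant VAFs between two lesions
#'
#' Identifies variants present in both lesions of a case (same
#' `(chrom, pos, ref, alt)` key) and compares their VAF collections
#' with a two-sided Wilcoxon rank-sum test, reporting per-lesion means.
#'
#' @param somaticTable filtered somatic variant data.frame of one case.
#' @param roleA,roleB the two lesion roles (defaults `L` and `G`).
#' @return list with `nShared`, `meanA`, `meanB`, `meanDifference`
#'   (B - A) and `test` (a [TestResult-class]).
#' @export
sharedVafComparison <- function(somaticTable, roleA = "L", roleB = "G") {
  a <- somaticTable[somaticTable$role == roleA, , drop = FALSE]
  b <- somaticTable[somaticTable$role == roleB, , drop = FALSE]
  keys <- intersect(.variantKey(a), .variantKey(b))
  if (!length(keys))
    stop("no shared variants between ", roleA, " and ", roleB,
         call. = FALSE)
  va <- a$vaf[match(keys, .variantKey(a))]
  vb <- b$vaf[match(keys, .variantKey(b))]
  list(nShared = length(keys), meanA = mean(va), meanB = mean(vb),
       meanDifference = mean(vb) - mean(va),
       test = wilcoxonRankSum(va, vb,
                              groupNames = c(roleA, roleB)))
}

#' Maximum-likelihood topology cross-check
#'
#' Secondary scorer for robustness: fits a two-state Markov model
#' (equal rates, the binary analogue of the Jukes-Cantor model) on each
#' candidate topology with `phangorn` and returns the classification of
#' the best-likelihood topology. Concordance with the parsimony result
#' is reported by the caller, never enforced.
#'
#' @param bcm a [BinaryCharacterMatrix-class].
#' @return one of "TYPE1", "TYPE2", "TYPE3", "UNRESOLVED", or NA when
#'   `phangorn` is unavailable or the fit fails.
#' @export
mlTopologyCheck <- function(bcm) {
  if (!requireNamespace("phangorn", quietly = TRUE)) return(NA_character_)
  if (ncol(bcm@mat) == 0L || length(bcm@taxa) != 4L) return(NA_character_)
  out <- tryCatch({
    dat <- phangorn::phyDat(bcm@mat, type = "USER", levels = c(0L, 1L))
    others <- setdiff(bcm@taxa, c("Nm", "N", "L", "G"))
    if (length(others)) return(NA_character_)
    cherries <- list(TYPE1 = c("L", "G"), TYPE2 = c("N", "L"),
                     TYPE3 = c("N", "G"))
    lik <- vapply(cherries, function(pair) {
      rest <- setdiff(bcm@taxa, pair)
      nwk <- sprintf("((%s:0.1,%s:0.1):0.1,(%s:0.1,%s:0.1):0.1);",
                     pair[1], pair[2], rest[1], rest[2])
      fit <- phangorn::pml(ape::read.tree(text = nwk), dat)
      fit <- suppressWarnings(
        phangorn::optim.pml(fit, optEdge = TRUE,
                            control = phangorn::pml.control(trace = 0)))
      fit$logLik
    }, numeric(1))
    winners <- which(lik > max(lik) - 1e-6)
    if (length(winners) > 1L) "UNRESOLVED" else names(cherries)[winners]
  }, error = function(e) NA_character_)
  out
}
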