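# CpG-to-gene assignment: a three-rule proximity cascade.
#
#   rule 1 (gene_body_4kb):    within 4 kb of a gene body -> that gene
#   rule 2 (neighbor_cpg):     else, within `neighbor_radius` of a CpG
#                              already assigned by rule 1 -> inherit its gene
#   rule 3 (nearest_prc2_200kb): else, nearest PRC2 target gene body within
#                              200 kb -> that gene
#   otherwise unassigned.
#
# Distance from a CpG at 0-based position p to a half-open gene body
# [start, end) is 0 inside, start - p upstream, p - (end - 1) downstream.
# Ties break by smaller distance, then lexicographic gene id. Rule 2
# inherits only from rule-1 assignments (no transitive chaining).

# distance of each pos to each gene body on one chromosome (genes as
# columns); small dense matrix, used at module scale and as the clear
# definition the faster paths must agree with
.body_dist <- function(pos, start, end) {
  up <- outer(start, pos, function(s, p) s - p)     # genes x pos
  down <- outer(end - 1L, pos, function(e, p) p - e)
  d <- pmax(up, down)
  d[d < 0] <- 0
  d
}

.nearest_gene <- function(cpgs, annotation) {
  # per CpG: nearest gene body distance + gene id (ties: smaller distance
  # then lexicographic id)
  n <- nrow(cpgs)
  dist <- rep(NA_real_, n)
  gene <- rep(NA_character_, n)
  if (nrow(annotation) == 0L || n == 0L)
    return(data.frame(gene = gene, dist = dist))
  ord <- order(annotation$gene_id)  # lexicographic tie-break via which.min
  ann <- annotation[ord, , drop = FALSE]
  for (ch in unique(as.character(cpgs$chrom))) {
    ci <- which(cpgs$chrom == ch)
    gi <- which(ann$chrom == ch)
    if (length(gi) == 0L) next
    d <- .body_dist(cpgs$pos[ci], ann$start[gi], ann$end[gi])
    best <- apply(d, 2L, which.min)
    dist[ci] <- d[cbind(best, seq_along(ci))]
    gene[ci] <- ann$gene_id[gi][best]
  }
  data.frame(gene = gene, dist = dist)
}

#' Assign all CpGs to genes by the proximity cascade
#'
#' Two passes: pass 1 applies the 4 kb gene-body rule to every CpG; pass 2
#' walks the remaining CpGs in coordinate order applying the
#' neighbor-inheritance rule (from rule-1 assignments only) and then the
#' nearest-PRC2-target rule. Deterministic for fixed input.
#'
#' @param cpgs data.frame `chrom`, `pos` (0-based CpG positions).
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), sorted by (chrom, start).
#' @param prc2_targets Character vector of PRC2 target gene ids (must be a
#'   subset of the annotation).
#' @param body_radius Rule-1 distance bound in bp (default 4000).
#' @param neighbor_radius Rule-2 distance bound in bp (default 1000).
#' @param prc2_radius Rule-3 distance bound in bp (default 200000).
#' @return data.frame `chrom`, `pos`, `gene_id` (NA if unassigned),
#'   `rule` (factor gene_body_4kb / neighbor_cpg / nearest_prc2_200kb /
#'   unassigned), `distance` (bp; NA if unassigned).
#' @export
assign_all <- function(cpgs, annotation, prc2_targets = character(),
                       body_radius = 4000, neighbor_radius = 1000,
                       prc2_radius = 200000) {
  if (nrow(annotation) > 1L) {
    o <- order(annotation$chrom, annotation$start)
    if (!identical(o, seq_len(nrow(annotation))))
      .stopf("annotation must be sorted by (chrom, start)")
  }
  bad <- setdiff(prc2_targets, annotation$gene_id)
  if (length(bad)) .stopf("PRC2 target(s) not in annotation: %s",
                          paste(utils::head(bad, 3), collapse = ", "))
  n <- nrow(cpgs)
  ord <- order(cpgs$chrom, cpgs$pos)
  cp <- cpgs[ord, c("chrom", "pos"), drop = FALSE]
  gene <- rep(NA_character_, n)
  rule <- rep("unassigned", n)
  dist <- rep(NA_real_, n)

  # pass 1: gene body rule
  nb <- .nearest_gene(cp, annotation)
  hit1 <- !is.na(nb$dist) & nb$dist <= body_radius
  gene[hit1] <- nb$gene[hit1]
  rule[hit1] <- "gene_body_4kb"
  dist[hit1] <- nb$dist[hit1]

  # pass 2: neighbor inheritance (rule-1 donors only), then PRC2 rule
  rest <- which(!hit1)
  if (length(rest)) {
    targets <- annotation[annotation$gene_id %in% prc2_targets, , drop = FALSE]
    np <- .nearest_gene(cp[rest, , drop = FALSE], targets)
    for (k in seq_along(rest)) {
      i <- rest[k]
      donors <- which(hit1 & cp$chrom == cp$chrom[i] &
                        abs(cp$pos - cp$pos[i]) <= neighbor_radius)
      if (length(donors)) {
        dd <- abs(cp$pos[donors] - cp$pos[i])
        o <- order(dd, gene[donors])
        gene[i] <- gene[donors[o[1]]]
        rule[i] <- "neighbor_cpg"
        dist[i] <- dd[o[1]]
      } else if (!is.na(np$dist[k]) && np$dist[k] <= prc2_radius) {
        gene[i] <- np$gene[k]
        rule[i] <- "nearest_prc2_200kb"
        dist[i] <- np$dist[k]
      }
    }
  }
  data.frame(chrom = cp$chrom, pos = cp$pos, gene_id = gene,
             rule = factor(rule, levels = c("gene_body_4kb", "neighbor_cpg",
                                            "nearest_prc2_200kb",
                                            "unassigned")),
             distance = dist)
}

#' Assign a single CpG to a gene
#'
#' Single-site convenience wrapper over the cascade; rule-2 donors are the
#' supplied `existing_assignments` (rows with rule `gene_body_4kb`).
#'
#' @param chrom,pos CpG location (0-based).
#' @param annotation,prc2_targets,body_radius,neighbor_radius,prc2_radius
#'   As in [assign_all()].
#' @param existing_assignments Optional [assign_all()]-style data.frame of
#'   already-assigned CpGs available for neighbor inheritance.
#' @return One-row assignment data.frame (see [assign_all()]).
#' @export
assign_cpg_to_gene <- function(chrom, pos, annotation,
                               prc2_targets = character(),
                               existing_assignments = NULL,
                               body_radius = 4000, neighbor_radius = 1000,
                               prc2_radius = 200000) {
  lv <- c("gene_body_4kb", "neighbor_cpg", "nearest_prc2_200kb", "unassigned")
  cp <- data.frame(chrom = chrom, pos = pos)
  nb <- .nearest_gene(cp, annotation)
  if (!is.na(nb$dist[1]) && nb$dist[1] <= body_radius)
    return(data.frame(chrom = chrom, pos = pos, gene_id = nb$gene[1],
                      rule = factor("gene_body_4kb", levels = lv),
                      distance = nb$dist[1]))
  if (!is.null(existing_assignments)) {
    don <- existing_assignments[existing_assignments$rule == "gene_body_4kb" &
                                  existing_assignments$chrom == chrom, , drop = FALSE]
    if (nrow(don)) {
      dd <- abs(don$pos - pos)
      ok <- dd <= neighbor_radius
      if (any(ok)) {
        o <- order(dd[ok], don$gene_id[ok])
        return(data.frame(chrom = chrom, pos = pos,
                          gene_id = don$gene_id[ok][o[1]],
                          rule = factor("neighbor_cpg", levels = lv),
                          distance = dd[ok][o[1]]))
      }
    }
  }
  targets <- annotation[annotation$gene_id %in% prc2_targets, , drop = FALSE]
  np <- .nearest_gene(cp, targets)
  if (!is.na(np$dist[1]) && np$dist[1] <= prc2_radius)
    return(data.frame(chrom = chrom, pos = pos, gene_id = np$gene[1],
                      rule = factor("nearest_prc2_200kb", levels = lv),
                      distance = np$dist[1]))
  data.frame(chrom = chrom, pos = pos, gene_id = NA_character_,
             rule = factor("unassigned", levels = lv), distance = NA_real_)
}
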