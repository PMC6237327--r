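#' Read a candidate biomarker list
#'
#' CSV with columns \code{name}, and optionally \code{alt_name},
#' \code{p}, \code{direction}, \code{source}. The working name of an
#' entry is \code{alt_name} when present (the current gene annotation),
#' otherwise \code{name}; entries resolving case-insensitively to the
#' same working name are collapsed to one (sources concatenated), so
#' names are unique after alternate resolution.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{name}, \code{alt_name},
#'   \code{resolved}, \code{p}, \code{direction}, \code{source}.
#' @export
readCandidateList <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) stop("candidate list needs a 'name' column")
  for (col in c("alt_name", "direction", "source"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$p)) df$p <- NA_real_
  df$resolved <- ifelse(!is.na(df$alt_name) & nzchar(df$alt_name),
                        df$alt_name, df$name)
  key <- tolower(df$resolved)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    src <- tapply(df$source, key, function(s)
      paste(unique(s[!is.na(s)]), collapse = ";"))
    df <- df[first, , drop = FALSE]
    df$source <- unname(src[tolower(df$resolved)])
  }
  rownames(df) <- NULL
  df[c("name", "alt_name", "resolved", "p", "direction", "source")]
}

#' Read an identifier mapping table
#'
#' TSV with columns \code{external}, \code{internal}, \code{kind}
#' (homolog, alias or probeset). Many-to-many rows are allowed;
#' duplicated identical rows are dropped.
#'
#' @param path TSV file path.
#' @return data.frame of mapping rows.
#' @export
readMappingTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("external", "internal") %in% names(df)))
    stop("mapping table needs columns 'external' and 'internal'")
  if (is.null(df$kind)) df$kind <- "alias"
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Map candidate names into the internal gene namespace
#'
#' Case-insensitive lookup of each candidate's resolved name in the
#' mapping table. One-to-many mappings expand to one row per internal
#' gene with provenance retained; candidates without any mapping row are
#' returned separately, never dropped silently.
#'
#' @param candidates data.frame from \code{\link{readCandidateList}} (or
#'   any data.frame with a \code{resolved} or \code{name} column).
#' @param mapping data.frame from \code{\link{readMappingTable}}.
#' @return list with \code{mapped} (candidate columns plus
#'   \code{internal}, \code{kind}) and \code{unmatched}.
#' @export
mapCandidates <- function(candidates, mapping) {
  if (is.null(candidates$resolved))
    candidates$resolved <- candidates$name
  if (nrow(mapping) == 0 && nrow(candidates) > 0) {
    warning("empty mapping table: all candidates unmatched")
    return(list(mapped = cbind(candidates[0, , drop = FALSE],
                               internal = character(0),
                               kind = character(0)),
                unmatched = candidates))
  }
  key <- tolower(mapping$external)
  hits <- lapply(seq_len(nrow(candidates)), function(i) {
    j <- which(key == tolower(candidates$resolved[i]))
    if (!length(j)) return(NULL)
    cbind(candidates[rep(i, length(j)), , drop = FALSE],
          internal = mapping$internal[j], kind = mapping$kind[j])
  })
  mapped <- do.call(rbind, hits)
  if (is.null(mapped))
    mapped <- cbind(candidates[0, , drop = FALSE],
                    internal = character(0), kind = character(0))
  rownames(mapped) <- NULL
  matched_idx <- vapply(seq_len(nrow(candidates)), function(i)
    any(key == tolower(candidates$resolved[i])), logical(1))
  unmatched <- candidates[!matched_idx, , drop = FALSE]
  rownames(unmatched) <- NULL
  list(mapped = mapped, unmatched = unmatched)
}

#' Read a published ranking table
#'
#' TSV transcription of a printed ranking (rank, p_value, probe_id,
#' gene). "NS" entries carry an empty rank and p cell and become NA.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{gene_id}, \code{p}, \code{rank},
#'   \code{probe_id}.
#' @export
readRankingTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("", "NA", "NS", "~"))
  names(df) <- tolower(names(df))
  p_col <- intersect(c("p", "p_value", "pvalue"), names(df))[1]
  g_col <- intersect(c("gene_id", "gene", "gene_name"), names(df))[1]
  if (is.na(p_col) || is.na(g_col))
    stop("ranking table needs gene and p-value columns")
  out <- data.frame(gene_id = df[[g_col]],
                    p = as.numeric(df[[p_col]]),
                    rank = if ("rank" %in% names(df))
                      as.numeric(df$rank) else NA_real_,
                    probe_id = if ("probe_id" %in% names(df))
                      as.character(df$probe_id) else NA_character_,
                    stringsAsFactors = FALSE)
  out
}

#' Locate mapped candidates in a significance ranking
#'
#' Annotates each mapped candidate with the rank and p-value of its
#' internal gene in a ranking (a \code{\link{rankAndThreshold}} table or
#' a transcription of a printed table). Genes absent from the ranking or
#' present without a p-value (NS) are flagged, not dropped.
#'
#' @param mapped data.frame with an \code{internal} column (from
#'   \code{\link{mapCandidates}$mapped}).
#' @param ranking data.frame with \code{gene_id}, \code{p} and optionally
#'   \code{rank}.
#' @return the mapped table with added \code{rank}, \code{p},
#'   \code{in_ranking} and \code{ns} columns.
#' @export
locateInRanking <- function(mapped, ranking) {
  if (is(ranking, "ModeratedResult")) ranking <- resultTable(ranking)
  idx <- match(tolower(mapped$internal), tolower(ranking$gene_id))
  out <- mapped
  out$rank <- if ("rank" %in% names(ranking)) ranking$rank[idx]
              else NA_real_
  out$p <- ranking$p[idx]
  out$in_ranking <- !is.na(idx)
  out$ns <- out$in_ranking & is.na(out$p)
  out
}

#' Count candidates passing a significance cutoff
#'
#' NS entries (no p-value printed) count as p = 1, i.e. never
#' significant.
#'
#' @param rank_table data.frame with a \code{p} column.
#' @param alpha cutoff in (0, 1).
#' @return integer count of rows with p < alpha.
#' @export
countSignificant <- function(rank_table, alpha = 5e-7) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  sum(!is.na(rank_table$p) & rank_table$p < alpha)
}

#' Condition-specificity partition of up/down gene lists
#'
#' Given the up- and downregulated gene lists of two conditions (e.g.
#' ischemic stroke vs sham surgery), computes per direction the genes
#' exclusive to each condition and the shared genes, as in a two-set
#' Venn diagram.
#'
#' @param up1,down1 character vectors for condition 1.
#' @param up2,down2 character vectors for condition 2.
#' @return nested list \code{$up} and \code{$down}, each with
#'   \code{exclusive1}, \code{exclusive2}, \code{shared} and
#'   \code{counts}.
#' @examples
#' vennPartition(c("a", "b"), character(), "c", character())$up$counts
#' @export
vennPartition <- function(up1, down1, up2, down2) {
  part <- function(l1, l2) {
    l1 <- unique(l1)
    l2 <- unique(l2)
    sh <- intersect(l1, l2)
    res <- list(exclusive1 = setdiff(l1, l2),
                exclusive2 = setdiff(l2, l1),
                shared = sh)
    res$counts <- c(exclusive1 = length(res$exclusive1),
                    exclusive2 = length(res$exclusive2),
                    shared = length(sh))
    res
  }
  list(up = part(up1, up2), down = part(down1, down2))
}

#' Export a heat-map matrix of centered profiles for a gene subset
#'
#' @param profiles genes x timepoints averaged profile matrix.
#' @param gene_subset gene IDs to include; members absent from the
#'   profiles are reported in the \code{missing} element.
#' @param ordering \code{"given"} (subset order) or \code{"by_p"}
#'   (ascending p).
#' @param p named p-values (required for \code{ordering = "by_p"}).
#' @return list with \code{matrix} (mean-centered rows, ordered) and
#'   \code{missing}.
#' @export
heatmapMatrix <- function(profiles, gene_subset,
                          ordering = c("given", "by_p"), p = NULL) {
  ordering <- match.arg(ordering)
  gene_subset <- as.character(gene_subset)
  if (!length(gene_subset)) stop("empty gene subset")
  present <- gene_subset[gene_subset %in% rownames(profiles)]
  missing <- setdiff(gene_subset, present)
  if (!length(present)) stop("no subset member found in the profiles")
  if (ordering == "by_p") {
    if (is.null(p)) stop("ordering by p requires p-values")
    present <- present[order(p[present])]
  }
  m <- profiles[present, , drop = FALSE]
  m <- m - rowMeans(m)
  list(matrix = m, missing = missing)
}
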