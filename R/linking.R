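#' Chromatin loops (paired anchors)
#'
#' A loop connects two genomic anchors, typically a promoter and a distal
#' regulatory site from promoter-capture Hi-C. Anchors live on one genome;
#' cis (same-chromosome) loops are the norm and trans loops are flagged.
#'
#' @param anchor1,anchor2 [interval_set()] objects of equal length.
#' @param name optional loop ids.
#' @param score optional numeric scores.
#' @return object of class `loop_set`: data frame with `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `name`, `score`, `trans`.
#' @export
loop_set <- function(anchor1, anchor2, name = NULL, score = NULL) {
  stopifnot(inherits(anchor1, "interval_set"), inherits(anchor2, "interval_set"))
  if (!same_genome(anchor1, anchor2)) stop2("anchors bound to different genomes")
  if (nrow(anchor1) != nrow(anchor2)) stop2("anchor sets differ in length")
  same <- anchor1$chrom == anchor2$chrom & anchor1$start == anchor2$start &
    anchor1$end == anchor2$end
  if (any(same)) stop2("loop with identical anchors at row ", which(same)[1])
  df <- data.frame(chrom1 = anchor1$chrom, start1 = anchor1$start, end1 = anchor1$end,
                   chrom2 = anchor2$chrom, start2 = anchor2$start, end2 = anchor2$end,
                   name = if (is.null(name)) sprintf("loop_%d", seq_len(nrow(anchor1))) else as.character(name),
                   score = if (is.null(score)) NA_real_ else as.numeric(score),
                   trans = anchor1$chrom != anchor2$chrom,
                   stringsAsFactors = FALSE)
  structure(df, genome = iv_genome(anchor1),
            class = c("loop_set", "data.frame"))
}

loop_anchor <- function(loops, which = 1) {
  g <- attr(loops, "genome")
  if (which == 1)
    interval_set(loops$chrom1, loops$start1, loops$end1, name = loops$name,
                 genome = g, role = "anchor1")
  else
    interval_set(loops$chrom2, loops$start2, loops$end2, name = loops$name,
                 genome = g, role = "anchor2")
}

#' Read / write BEDPE loop files
#'
#' Six or more tab-separated columns: chrom1, start1, end1, chrom2, start2,
#' end2, then optional name and score.
#'
#' @param path file path.
#' @param genome [genome()] for validation.
#' @return `read_bedpe` returns a [loop_set()].
#' @export
read_bedpe <- function(path, genome) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(f) == 0) {
    e <- interval_set(character(), numeric(), numeric(), genome = genome)
    return(loop_set(e, e))
  }
  if (any(lengths(f) < 6)) stop2("BEDPE requires >= 6 columns: ", path)
  col <- function(i) vapply(f, `[[`, "", i)
  a1 <- interval_set(col(1), as.numeric(col(2)), as.numeric(col(3)), genome = genome)
  a2 <- interval_set(col(4), as.numeric(col(5)), as.numeric(col(6)), genome = genome)
  nm <- if (any(lengths(f) >= 7)) vapply(f, function(x) if (length(x) >= 7) x[[7]] else NA_character_, "") else NULL
  sc <- if (any(lengths(f) >= 8))
    suppressWarnings(vapply(f, function(x) if (length(x) >= 8) as.numeric(x[[8]]) else NA_real_, 0)) else NULL
  loop_set(a1, a2, name = nm, score = sc)
}

#' @rdname read_bedpe
#' @param x a [loop_set()].
#' @export
write_bedpe <- function(x, path) {
  stopifnot(inherits(x, "loop_set"))
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  sc <- ifelse(is.na(x$score), ".", fmt(x$score))
  writeLines(paste(x$chrom1, fmt(x$start1), fmt(x$end1),
                   x$chrom2, fmt(x$start2), fmt(x$end2), x$name, sc,
                   sep = "\t"), path)
  invisible(path)
}

#' Flank both loop anchors symmetrically
#'
#' Extends each anchor by `flank_bp` on both sides (clamped to the
#' chromosome), the 5 kb window conventionally applied around pcHi-C loop
#' anchors before intersecting them with sites and promoters.
#'
#' @param loops a [loop_set()].
#' @param flank_bp flank in bp (default 5000).
#' @return a [loop_set()] with flanked anchors.
#' @export
flank_anchors <- function(loops, flank_bp = 5000) {
  stopifnot(inherits(loops, "loop_set"), flank_bp >= 0)
  loop_set(extend_intervals(loop_anchor(loops, 1), flank_bp),
           extend_intervals(loop_anchor(loops, 2), flank_bp),
           name = loops$name, score = loops$score)
}

#' Variant association table
#'
#' @param chrom chromosome per variant.
#' @param pos 0-based position in bp (must lie on the chromosome).
#' @param id variant ids (unique).
#' @param p association p-values in (0, 1].
#' @param genome [genome()] for validation.
#' @return object of class `variant_table` (data frame).
#' @export
variant_table <- function(chrom, pos, id, p, genome) {
  stopifnot(inherits(genome, "genome"))
  chrom <- as.character(chrom); pos <- as.numeric(pos)
  id <- as.character(id); p <- as.numeric(p)
  n <- max(length(chrom), length(pos))
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(pos) == n, length(id) == n,
            length(p) == n)
  if (anyDuplicated(id)) stop2("variant ids must be unique")
  if (n > 0) {
    if (any(!chrom %in% names(genome)))
      stop2("variant on unknown chromosome")
    if (any(pos < 0) || any(pos >= unclass(genome)[chrom]))
      stop2("variant position outside chromosome")
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop2("p-values must lie in (0, 1]")
  }
  structure(data.frame(chrom = chrom, pos = pos, id = id, p = p,
                       stringsAsFactors = FALSE),
            genome = genome, class = c("variant_table", "data.frame"))
}

#' Read / write variant tables (TSV: chrom, pos, id, p)
#' @param path file path.
#' @param genome [genome()] for validation.
#' @return `read_variants` returns a [variant_table()].
#' @export
read_variants <- function(path, genome) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "p")
  if (!all(need %in% names(d)))
    stop2("variant table needs columns: ", paste(need, collapse = ", "))
  variant_table(d$chrom, d$pos, d$id, d$p, genome)
}

#' @rdname read_variants
#' @param x a [variant_table()].
#' @export
write_variants <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep variants with at least nominal association
#'
#' Strict inequality: a variant with `p` exactly equal to `alpha` is
#' excluded.
#'
#' @param variants a [variant_table()].
#' @param alpha cutoff (default 0.05).
#' @return the filtered [variant_table()].
#' @export
filter_variants <- function(variants, alpha = 0.05) {
  stopifnot(inherits(variants, "variant_table"))
  out <- as.data.frame(variants)[variants$p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome = attr(variants, "genome"),
            class = c("variant_table", "data.frame"))
}

#' Link sites to genes through chromatin loops
#'
#' A site links to a gene via a loop when the site overlaps one flanked
#' anchor and the gene's promoter (TSS, optionally widened by
#' `promoter_window`) lies within the other flanked anchor. Links are
#' many-to-many, deduplicated over (site, gene, loop), sorted, and invariant
#' to anchor order.
#'
#' @param sites [interval_set()] of bound sites; names become site ids.
#' @param loops a [loop_set()].
#' @param promoters [interval_set()] of TSS positions whose `name` carries
#'   the gene id (an unnamed promoter is an error).
#' @param flank_bp flank applied to both anchors (default 5000).
#' @param promoter_window symmetric extension of each promoter in bp
#'   (default 0: the TSS point itself).
#' @return data frame with `site_id`, `gene_id`, `loop_id`, `trans`.
#' @export
link_sites_to_genes <- function(sites, loops, promoters, flank_bp = 5000,
                                promoter_window = 0) {
  stopifnot(inherits(sites, "interval_set"), inherits(loops, "loop_set"),
            inherits(promoters, "interval_set"))
  if (is.null(promoters$name) || any(is.na(promoters$name) | !nzchar(promoters$name)))
    stop2("every promoter must carry a gene id in its name field")
  g <- iv_genome(sites)
  offs <- genome_offsets(g)
  site_id <- sites$name %||% sprintf("site_%d", seq_len(nrow(sites)))
  fl <- flank_anchors(loops, flank_bp)
  prom <- if (promoter_window > 0) extend_intervals(promoters, promoter_window) else promoters
  sg <- global_coords(sites, offs)
  pg <- global_coords(prom, offs)
  rows <- vector("list", nrow(fl))
  for (i in seq_len(nrow(fl))) {
    a1s <- offs[fl$chrom1[i]] + fl$start1[i]; a1e <- offs[fl$chrom1[i]] + fl$end1[i]
    a2s <- offs[fl$chrom2[i]] + fl$start2[i]; a2e <- offs[fl$chrom2[i]] + fl$end2[i]
    s1 <- sg$s < a1e & sg$e > a1s      # sites on anchor 1
    s2 <- sg$s < a2e & sg$e > a2s
    p1 <- pg$s < a1e & pg$e > a1s      # promoters on anchor 1
    p2 <- pg$s < a2e & pg$e > a2s
    pair <- rbind(
      if (any(s1) && any(p2)) expand.grid(site = which(s1), prom = which(p2)),
      if (any(s2) && any(p1)) expand.grid(site = which(s2), prom = which(p1)))
    if (is.null(pair) || nrow(pair) == 0) next
    rows[[i]] <- data.frame(site_id = site_id[pair$site],
                            gene_id = prom$name[pair$prom],
                            loop_id = fl$name[i], trans = fl$trans[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(site_id = character(), gene_id = character(),
                      loop_id = character(), trans = logical(),
                      stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$site_id, out$gene_id, out$loop_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene set linked to variant-bearing bound sites
#'
#' Restricts sites to those containing at least one retained variant
#' (position inside the raw, unflanked site unless `variant_in_flanked`),
#' links the qualifying sites to genes through loops, and returns the
#' distinct linked genes together with the fully annotated link table
#' (site, variant, gene, loop). The gene set is ready for
#' [gsea_preranked()].
#'
#' @param sites,loops,promoters as in [link_sites_to_genes()].
#' @param variants a [variant_table()].
#' @param alpha variant retention cutoff, strict `<` (default 0.05).
#' @param flank_bp anchor flank in bp (default 5000).
#' @param promoter_window promoter extension in bp (default 0).
#' @param variant_in_flanked when TRUE, a variant inside the `flank_bp`-
#'   extended site also qualifies (default FALSE: raw site only).
#' @return list with `genes` (sorted character vector) and `links`
#'   (data frame: `site_id`, `variant_id`, `gene_id`, `loop_id`).
#' @export
variant_linked_geneset <- function(sites, variants, loops, promoters,
                                   alpha = 0.05, flank_bp = 5000,
                                   promoter_window = 0,
                                   variant_in_flanked = FALSE) {
  stopifnot(inherits(sites, "interval_set"), inherits(variants, "variant_table"))
  kept <- filter_variants(variants, alpha)
  site_id <- sites$name %||% sprintf("site_%d", seq_len(nrow(sites)))
  win <- if (variant_in_flanked) extend_intervals(sites, flank_bp) else sites
  g <- iv_genome(sites)
  offs <- genome_offsets(g)
  vpos <- offs[kept$chrom] + kept$pos
  wg <- global_coords(win, offs)
  # variant -> site containment (a position is the 1 bp interval [pos, pos+1))
  hit <- lapply(seq_len(nrow(win)), function(i)
    which(vpos >= wg$s[i] & vpos < wg$e[i]))
  qual <- which(lengths(hit) > 0)
  if (length(qual) == 0)
    return(list(genes = character(),
                links = data.frame(site_id = character(), variant_id = character(),
                                   gene_id = character(), loop_id = character(),
                                   stringsAsFactors = FALSE)))
  qsites <- sites[qual]
  attr(qsites, "role") <- attr(sites, "role")
  links <- link_sites_to_genes(qsites, loops, promoters, flank_bp = flank_bp,
                               promoter_window = promoter_window)
  vmap <- data.frame(site_id = rep(site_id[qual], lengths(hit[qual])),
                     variant_id = kept$id[unlist(hit[qual])],
                     stringsAsFactors = FALSE)
  ann <- merge(links, vmap, by = "site_id")
  ann <- unique(ann[c("site_id", "variant_id", "gene_id", "loop_id")])
  ann <- ann[order(ann$site_id, ann$variant_id, ann$gene_id, ann$loop_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(genes = sort(unique(links$gene_id)), links = ann)
}
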