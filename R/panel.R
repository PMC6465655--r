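# Canonical chromosome order used everywhere: autosomes 1..22, then X, Y.
CHROMS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

#' GRCh37-style chromosome sizes
#'
#' Chromosome lengths (bp) of the human GRCh37/hg19 assembly, used as the
#' default coordinate system for synthetic panel layouts.
#'
#' @return Named integer-ish numeric vector over chromosomes 1-22, X, Y.
#' @export
default_chrom_sizes <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

chrom_factor <- function(chrom) factor(as.character(chrom), levels = CHROMS)

new_panel <- function(df, backbone_length = NULL) {
  df$chrom <- as.character(df$chrom)
  o <- order(chrom_factor(df$chrom), df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(backbone_length)) {
    bl <- unique(df$end[df$kind == "backbone"] - df$start[df$kind == "backbone"])
    backbone_length <- if (length(bl) == 1L) bl else NA_integer_
  }
  structure(df, class = c("nipt_panel", "data.frame"),
            backbone_length = backbone_length)
}

#' Construct a target capture panel
#'
#' A panel is an ordered table of target regions. Backbone regions are the
#' equal-length counting regions used for aneuploidy/CNV statistics; hotspot
#' regions tile single-gene mutation hotspots and carry a gene label.
#' Coordinates are 0-based half-open (BED convention) internally and on disk.
#'
#' @param chrom Chromosome names ("1"-"22", "X", "Y").
#' @param start,end 0-based half-open coordinates (bp).
#' @param kind "backbone" or "hotspot".
#' @param gc GC fraction in \[0,1\] (constant by panel design; default 0.5).
#' @param gene Gene label, required for hotspot regions.
#' @return A `nipt_panel` (data.frame subclass) sorted by (chrom, start).
#' @export
nipt_panel <- function(chrom, start, end, kind, gc = 0.5, gene = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), kind = as.character(kind),
                   gc = as.numeric(gc), gene = as.character(gene),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start))
    stop("panel regions must satisfy end > start")
  if (!all(df$kind %in% c("backbone", "hotspot")))
    stop("region kind must be 'backbone' or 'hotspot'")
  if (any(df$gc < 0 | df$gc > 1, na.rm = TRUE))
    stop("gc must lie in [0, 1]")
  if (!all(df$chrom %in% CHROMS))
    stop("unknown chromosome name(s): ",
         paste(unique(setdiff(df$chrom, CHROMS)), collapse = ", "))
  new_panel(df)
}

#' @export
print.nipt_panel <- function(x, ...) {
  nb <- sum(x$kind == "backbone"); nh <- sum(x$kind == "hotspot")
  cat(sprintf("<nipt_panel> %d regions: %d backbone (length %s bp), %d hotspot\n",
              nrow(x), nb, format(attr(x, "backbone_length")), nh))
  if (nh > 0)
    cat("  hotspot genes:", paste(sort(unique(stats::na.omit(x$gene))), collapse = ", "), "\n")
  invisible(x)
}

# Index helpers over the backbone (panel order restricted to backbone rows).
backbone_panel <- function(panel) panel[panel$kind == "backbone", , drop = FALSE]
backbone_scope <- function(panel, scope = c("autosomal", "whole")) {
  scope <- match.arg(scope)
  bb <- backbone_panel(panel)
  if (scope == "autosomal") which(bb$chrom %in% AUTOSOMES) else seq_len(nrow(bb))
}

panel_checksum <- function(panel) {
  bb <- backbone_panel(panel)
  key <- paste(bb$chrom, bb$start, bb$end, collapse = ";")
  # small rolling hash; only used to refuse scoring against a foreign baseline
  h <- 0
  for (blk in strsplit(key, "")[[1]]) h <- (h * 31 + utf8ToInt(blk)) %% 2147483647
  sprintf("%d-%d", nrow(bb), h)
}

#' Generate a synthetic panel layout
#'
#' Distributes `n_backbone` equal-length backbone regions across chromosomes
#' proportionally to chromosome length (largest-remainder apportionment, with
#' optional fixed per-chromosome counts), evenly spaced within each chromosome,
#' and appends the given hotspot windows. The layout is deterministic for a
#' fixed configuration and seed.
#'
#' @param chrom_sizes Named vector of chromosome sizes (bp).
#' @param n_backbone Total number of backbone regions.
#' @param backbone_length Length (bp) of every backbone region.
#' @param hotspot_spec Named list: gene -> data.frame(chrom, start, end) of
#'   hotspot windows, or NULL for a backbone-only panel.
#' @param seed Integer seed (reserved for optional jitter; the default layout
#'   is deterministic).
#' @param fixed_counts Optional named vector forcing the backbone count of
#'   specific chromosomes (e.g. c(Y = 88)); remaining regions are apportioned
#'   over the other chromosomes.
#' @param gc Constant GC fraction assigned to every region.
#' @return A `nipt_panel`.
#' @export
generate_panel_layout <- function(chrom_sizes, n_backbone, backbone_length,
                                  hotspot_spec = NULL, seed = 1,
                                  fixed_counts = NULL, gc = 0.5) {
  chrom_sizes <- chrom_sizes[order(chrom_factor(names(chrom_sizes)))]
  if (n_backbone < length(chrom_sizes))
    stop("n_backbone must be at least the number of chromosomes")
  if (backbone_length >= min(chrom_sizes))
    stop("backbone_length must be smaller than the smallest chromosome")

  counts <- apportion_counts(chrom_sizes, n_backbone, fixed_counts)

  rows <- lapply(names(chrom_sizes), function(cn) {
    n <- counts[[cn]]
    if (n == 0) return(NULL)
    L <- chrom_sizes[[cn]]
    stride <- L / n
    if (stride <= backbone_length)
      stop("backbone spacing infeasible on chromosome ", cn,
           ": regions would overlap")
    start <- round((seq_len(n) - 0.5) * stride - backbone_length / 2)
    start <- pmin(pmax(start, 0), L - backbone_length)
    data.frame(chrom = cn, start = start, end = start + backbone_length,
               kind = "backbone", gc = gc, gene = NA_character_,
               stringsAsFactors = FALSE)
  })
  bb <- do.call(rbind, rows)

  hs <- NULL
  if (!is.null(hotspot_spec) && length(hotspot_spec)) {
    hs <- do.call(rbind, lapply(names(hotspot_spec), function(g) {
      w <- as.data.frame(hotspot_spec[[g]])
      data.frame(chrom = as.character(w$chrom), start = as.numeric(w$start),
                 end = as.numeric(w$end), kind = "hotspot", gc = gc,
                 gene = g, stringsAsFactors = FALSE)
    }))
    # nudge any hotspot window off a backbone region (backbone layout is fixed)
    for (i in seq_len(nrow(hs))) {
      repeat {
        ov <- which(bb$chrom == hs$chrom[i] &
                    bb$start < hs$end[i] & hs$start[i] < bb$end)
        if (!length(ov)) break
        shift <- max(bb$end[ov]) - hs$start[i] + 1
        hs$start[i] <- hs$start[i] + shift
        hs$end[i] <- hs$end[i] + shift
      }
    }
  }

  panel <- new_panel(rbind(bb, hs), backbone_length = backbone_length)
  rep <- validate_panel(panel)
  if (nrow(rep))
    stop("generated layout violates panel invariants: ",
         paste(rep$message, collapse = "; "))
  panel
}

# Largest-remainder apportionment of n among chromosomes by size, with
# optional fixed counts for named chromosomes.
apportion_counts <- function(chrom_sizes, n, fixed_counts = NULL) {
  counts <- stats::setNames(rep(0L, length(chrom_sizes)), names(chrom_sizes))
  free <- names(chrom_sizes)
  if (!is.null(fixed_counts)) {
    counts[names(fixed_counts)] <- as.integer(fixed_counts)
    free <- setdiff(free, names(fixed_counts))
    n <- n - sum(fixed_counts)
    if (n < 0) stop("fixed_counts exceed n_backbone")
  }
  if (length(free)) {
    quota <- n * chrom_sizes[free] / sum(chrom_sizes[free])
    base <- floor(quota)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    counts[free] <- as.integer(base)
  }
  counts
}

#' Paper-scale demonstration panel
#'
#' The synthetic stand-in for the study's capture design: 8,171 equal-length
#' backbone regions (7,631 autosomal, 452 on X, 88 on Y) plus 560 variable
#' length hotspot windows over six recessive-disease genes (GJB2, GJB3,
#' SLC26A4, HBB, PTS, PAH), 8,731 regions in total. Coordinates are synthetic;
#' only the counts, spacing and length structure mirror the real design.
#'
#' @param backbone_length Backbone region length in bp.
#' @param seed Integer seed (layout is deterministic).
#' @return A `nipt_panel` with 8,731 regions.
#' @export
paper_panel <- function(backbone_length = 100, seed = 1) {
  generate_panel_layout(default_chrom_sizes(), n_backbone = 8171,
                        backbone_length = backbone_length,
                        hotspot_spec = default_hotspot_spec(), seed = seed,
                        fixed_counts = c(X = 452, Y = 88))
}

#' Default hotspot window specification
#'
#' 560 variable-length windows tiling synthetic loci of the six panel genes
#' (hearing impairment: GJB2, GJB3, SLC26A4; beta-thalassemia: HBB;
#' hyperphenylalaninemia: PAH, PTS).
#'
#' @return Named list gene -> data.frame(chrom, start, end).
#' @export
default_hotspot_spec <- function() {
  anchors <- list(
    GJB3    = list(chrom = "1",  at = 35246000),
    SLC26A4 = list(chrom = "7",  at = 107301000),
    HBB     = list(chrom = "11", at = 5246000),
    PTS     = list(chrom = "11", at = 112097000),
    PAH     = list(chrom = "12", at = 103232000),
    GJB2    = list(chrom = "13", at = 20761000))
  n_win <- c(GJB3 = 93, SLC26A4 = 93, HBB = 94, PTS = 93, PAH = 93, GJB2 = 94)
  out <- lapply(names(anchors), function(g) {
    a <- anchors[[g]]; n <- n_win[[g]]
    i <- seq_len(n)
    len <- 80 + ((i * 37) %% 121)          # unequal lengths, 80-200 bp
    start <- a$at + (i - 1) * 500
    data.frame(chrom = a$chrom, start = start, end = start + len,
               stringsAsFactors = FALSE)
  })
  stats::setNames(out, names(anchors))
}

#' Validate a panel
#'
#' Report-only check of the panel invariants: positive-width sorted regions,
#' no overlap within a chromosome, a single backbone length, gene labels on
#' every hotspot region, GC within \[0,1\].
#'
#' @param panel A `nipt_panel`.
#' @return data.frame(code, message); zero rows iff the panel is valid.
#' @export
validate_panel <- function(panel) {
  findings <- list()
  add <- function(code, message)
    findings[[length(findings) + 1]] <<- data.frame(code = code,
                                                    message = message,
                                                    stringsAsFactors = FALSE)
  bad <- which(panel$end <= panel$start)
  for (i in bad)
    add("empty_region", sprintf("region %s:%.0f-%.0f has end <= start",
                                panel$chrom[i], panel$start[i], panel$end[i]))
  for (cn in unique(panel$chrom)) {
    p <- panel[panel$chrom == cn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1) {
      ov <- which(p$start[-1] < p$end[-nrow(p)])
      for (i in ov)
        add("overlap", sprintf("regions %s:%.0f-%.0f and %s:%.0f-%.0f overlap",
                               cn, p$start[i], p$end[i],
                               cn, p$start[i + 1], p$end[i + 1]))
    }
  }
  bl <- unique(panel$end[panel$kind == "backbone"] -
               panel$start[panel$kind == "backbone"])
  if (length(bl) > 1)
    add("backbone_length",
        sprintf("backbone regions have %d distinct lengths (%s)",
                length(bl), paste(sort(bl), collapse = ", ")))
  miss <- which(panel$kind == "hotspot" &
                (is.na(panel$gene) | panel$gene == ""))
  for (i in miss)
    add("missing_gene", sprintf("hotspot region %s:%.0f-%.0f has no gene label",
                                panel$chrom[i], panel$start[i], panel$end[i]))
  if (any(panel$gc < 0 | panel$gc > 1, na.rm = TRUE))
    add("gc_range", "gc values outside [0, 1]")
  if (length(findings)) do.call(rbind, findings)
  else data.frame(code = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Read a panel from a BED file
#'
#' BED4 with 0-based half-open coordinates; the name field is either
#' `backbone` or `hotspot|GENE`.
#'
#' @param path BED file path.
#' @return A validated `nipt_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  prescan_bed(path)
  gr <- rtracklayer::import(path, format = "BED")
  name <- S4Vectors::mcols(gr)$name
  if (is.null(name) || any(is.na(name)))
    stop("panel BED requires a name field ('backbone' or 'hotspot|GENE')")
  kind <- ifelse(startsWith(name, "hotspot"), "hotspot", "backbone")
  if (!all(name %in% "backbone" | startsWith(name, "hotspot|")))
    stop("unrecognized region name(s): ",
         paste(utils::head(setdiff(name, "backbone"), 3), collapse = ", "))
  gene <- ifelse(kind == "hotspot", sub("^hotspot\\|", "", name), NA_character_)
  panel <- nipt_panel(chrom = sub("^chr", "", as.character(GenomicRanges::seqnames(gr))),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      kind = kind, gene = gene)
  rep <- validate_panel(panel)
  if (nrow(rep))
    stop("panel failed validation: ", paste(rep$message, collapse = "; "))
  panel
}

# Light line-level scan so malformed records are reported with their line
# number (the importer's own errors lose that context).
prescan_bed <- function(path) {
  ln <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", ln) & nzchar(trimws(ln))
  for (i in which(keep)) {
    f <- strsplit(ln[i], "\t")[[1]]
    if (length(f) < 4)
      stop(sprintf("malformed BED record at line %d: expected 4 fields", i))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed BED record at line %d: non-numeric coordinates", i))
    if (e <= s)
      stop(sprintf("malformed BED record at line %d: end <= start", i))
  }
  invisible(TRUE)
}

#' Write a panel to a BED file
#'
#' @param panel A `nipt_panel`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  name <- ifelse(panel$kind == "hotspot",
                 paste0("hotspot|", panel$gene), "backbone")
  gr <- GenomicRanges::GRanges(panel$chrom,
                               IRanges::IRanges(start = panel$start + 1,
                                                end = panel$end),
                               name = name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
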