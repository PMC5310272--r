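#' Three-step strain-attribution pipeline
#'
#' The end-to-end analysis for amino-acid-producer cohorts: (1) MLST typing
#' and grouping determine each strain's presumed wild-type ancestor; (2)
#' within-group core-SNP trees show the breeding trajectory; (3) every
#' producer strain is compared against its presumed ancestor and all
#' variants are annotated.  ANI and pan-genome stages can be switched on for
#' a full cohort report.
#'
#' @name pipeline-module
NULL

#' Assemble and validate a pipeline configuration
#'
#' @param genomes named list of \linkS4class{AnnotatedGenome}, or a
#'   directory containing per-strain \code{<id>.fasta} + \code{<id>.gff3}
#'   (as written by [emitCohort()]).
#' @param wildType character vector of wild-type strain ids (or named
#'   logical over strains).
#' @param scheme optional \linkS4class{MLSTScheme}; defaults to the first
#'   wild-type strain's own locus sequences.
#' @param groupMaxDistance MLST group linkage threshold (differing loci).
#' @param aniBand species-demarcation band, percent.
#' @param clusterMinIdentity,clusterMinCoverage ortholog clustering
#'   thresholds (percent / fraction).
#' @param upstreamWindow nt upstream window for variant annotation.
#' @param nPermutations rarefaction permutations (pan-genome stage).
#' @param seed integer seed for all randomized stages.
#' @param withANI,withPanGenome enable the optional stages.
#' @return a \code{PipelineConfig} (validated list).
#' @export
pipelineConfig <- function(genomes, wildType, scheme = NULL,
                           groupMaxDistance = 2L, aniBand = c(95, 96),
                           clusterMinIdentity = 50, clusterMinCoverage = 0.5,
                           upstreamWindow = 100L, nPermutations = 100L,
                           seed = 1L, withANI = FALSE, withPanGenome = FALSE) {
  if (is.character(genomes) && length(genomes) == 1L) {
    genomes <- readCohortDir(genomes)
  }
  if (length(genomes) < 2L) stop("need >= 2 genomes")
  if (is.logical(wildType)) wildType <- names(wildType)[wildType]
  if (length(wildType) < 1L) stop("need >= 1 wild-type strain")
  if (!all(wildType %in% names(genomes))) {
    stop("unknown wild-type strain(s): ",
         paste(setdiff(wildType, names(genomes)), collapse = ", "))
  }
  stopifnot(groupMaxDistance >= 0L, groupMaxDistance <= 7L,
            length(aniBand) == 2L, aniBand[1L] <= aniBand[2L],
            clusterMinIdentity > 0, clusterMinIdentity <= 100,
            clusterMinCoverage > 0, clusterMinCoverage <= 1,
            upstreamWindow >= 0L, nPermutations >= 1L)
  structure(list(genomes = genomes, wildType = wildType, scheme = scheme,
                 groupMaxDistance = as.integer(groupMaxDistance),
                 aniBand = aniBand,
                 clusterMinIdentity = clusterMinIdentity,
                 clusterMinCoverage = clusterMinCoverage,
                 upstreamWindow = as.integer(upstreamWindow),
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed),
                 withANI = isTRUE(withANI),
                 withPanGenome = isTRUE(withPanGenome)),
            class = "PipelineConfig")
}

configHash <- function(config) {
  rlang::hash(list(
    thresholds = config[c("groupMaxDistance", "aniBand",
                          "clusterMinIdentity", "clusterMinCoverage",
                          "upstreamWindow", "nPermutations", "seed",
                          "withANI", "withPanGenome")],
    wildType = sort(config$wildType),
    inputs = lapply(config$genomes, function(g)
      rlang::hash(as.character(contigs(g))))))
}

#' Run the strain-attribution pipeline
#'
#' MLST typing, ST assignment, grouping, presumed-ancestor selection,
#' per-group core-SNP trees and per-strain variant tables versus the
#' presumed ancestor.  A strain in a group with no wild-type member is
#' compared against the nearest-profile group member instead, with an
#' explicit no-ancestor caveat.  Stage failures are recorded per strain or
#' group and the pipeline continues.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @return a \code{PipelineReport}: list with \code{st_table},
#'   \code{ancestors}, \code{trees}, \code{variants}, optional \code{ani}
#'   and \code{pangenome}, \code{failures} and \code{provenance}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  set.seed(config$seed)
  genomes <- config$genomes
  failures <- list()

  scheme <- config$scheme
  if (is.null(scheme)) {
    scheme <- mlstSchemeFromGenome(genomes[[config$wildType[1L]]])
  }
  typed <- typeStrains(genomes, scheme)
  if (nrow(typed$missing)) {
    failures$mlst <- typed$missing
  }
  ok <- !apply(is.na(typed$profiles[, MLST_LOCI]), 1L, any)
  stTable <- clusterGroups(assignSTs(typed$profiles[ok, , drop = FALSE]),
                           config$groupMaxDistance)

  wild <- stats::setNames(stTable$strains$strain %in% config$wildType,
                          stTable$strains$strain)
  anc <- list()
  for (id in stTable$strains$strain) {
    pa <- presumedAncestor(id, stTable, wild)
    caveat <- ""
    ancestor <- pa$ancestor
    if (is.na(ancestor)) {
      # group without wild type: fall back to the nearest-profile neighbour
      df <- stTable$strains
      grp <- df[df$group == df$group[df$strain == id] & df$strain != id, ]
      if (nrow(grp)) {
        m <- profileMatrix(df)
        d <- apply(m[match(grp$strain, df$strain), , drop = FALSE], 1L,
                   function(p) sum(p != m[match(id, df$strain), ]))
        ancestor <- sort(grp$strain[d == min(d)])[1L]
        caveat <- "no presumed ancestor: no wild-type strain in group; nearest group member used"
      } else {
        caveat <- "no presumed ancestor: singleton group without wild type"
      }
    } else if (length(pa$tied)) {
      caveat <- paste("tied wild types:", paste(pa$tied, collapse = ","))
    }
    anc[[id]] <- data.frame(strain = id, ancestor = ancestor,
                            distance = pa$distance, caveat = caveat,
                            stringsAsFactors = FALSE)
  }
  ancestors <- do.call(rbind, anc)
  rownames(ancestors) <- NULL

  trees <- list()
  for (g in sort(unique(stTable$strains$group))) {
    ids <- stTable$strains$strain[stTable$strains$group == g]
    if (length(ids) < 2L) next
    key <- paste0("group", g)
    trees[[key]] <- tryCatch({
      snp <- coreSNPSites(genomes[ids])
      njTree(snpDistanceMatrix(snp))
    }, error = function(e) {
      failures[[key]] <<- conditionMessage(e)
      NULL
    })
  }

  variants <- list()
  for (id in stTable$strains$strain) {
    a <- ancestors$ancestor[ancestors$strain == id]
    if (is.na(a) || a == id) next
    variants[[id]] <- tryCatch(
      compareStrainPair(genomes[[id]], genomes[[a]],
                        upstreamWindow = config$upstreamWindow),
      error = function(e) {
        failures[[paste0("variants_", id)]] <<- conditionMessage(e)
        NULL
      })
  }

  ani <- NULL
  if (config$withANI) {
    ani <- aniMatrix(genomes)
  }
  pangenome <- NULL
  if (config$withPanGenome) {
    cl <- clusterOrthologs(genomes, config$clusterMinIdentity,
                           config$clusterMinCoverage)
    pa <- buildPAMatrix(cl, names(genomes))
    traj <- rarefy(pa, config$nPermutations, seed = config$seed)
    pangenome <- list(clusters = cl, pa = pa, traj = traj,
                      fits = fitCurves(traj))
  }

  structure(list(
    st_table = stTable, ancestors = ancestors, trees = trees,
    variants = variants, ani = ani, pangenome = pangenome,
    failures = failures,
    provenance = list(package = "strainTrace",
                      version = as.character(utils::packageVersion("strainTrace")),
                      seed = config$seed,
                      config_hash = configHash(config))),
    class = "PipelineReport")
}

#' @export
print.PipelineReport <- function(x, ...) {
  df <- x$st_table$strains
  cat("PipelineReport:", nrow(df), "strains,",
      nrow(x$st_table$stProfiles), "STs,", length(unique(df$group)),
      "groups;", length(x$trees), "group tree(s);",
      length(x$variants), "strain(s) with variant tables\n")
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Render a pipeline report to files
#'
#' Writes the ST/group/ancestor table, per-group Newick trees, per-strain
#' variant tables (an explicit "no variants" line rather than a missing
#' file), and — when those stages ran — the ANI matrix and pan-genome fit
#' parameters as JSON.  All tables are plain TSV and parse back losslessly.
#'
#' @param report a \code{PipelineReport}.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
renderReport <- function(report, dir) {
  stopifnot(inherits(report, "PipelineReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  st <- merge(report$st_table$strains, report$ancestors, by = "strain",
              sort = FALSE)
  stPath <- file.path(dir, "st_table.tsv")
  utils::write.table(st[, c("strain", MLST_LOCI, "ST", "group", "ancestor",
                            "distance", "caveat")],
                     stPath, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, stPath)
  for (key in names(report$trees)) {
    if (is.null(report$trees[[key]])) next
    p <- file.path(dir, paste0("tree_", key, ".nwk"))
    ape::write.tree(report$trees[[key]], p)
    written <- c(written, p)
  }
  for (id in names(report$variants)) {
    p <- file.path(dir, paste0("variants_", id, ".tsv"))
    vt <- report$variants[[id]]$variants
    if (nrow(vt) == 0L) {
      writeLines("# no variants", p)
    } else {
      utils::write.table(vt, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    written <- c(written, p)
  }
  if (!is.null(report$ani)) {
    p <- file.path(dir, "ani_matrix.tsv")
    utils::write.table(data.frame(strain = rownames(report$ani), report$ani,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(report$pangenome)) {
    p <- file.path(dir, "pangenome_fits.json")
    f <- report$pangenome$fits
    jsonlite::write_json(list(
      pan = as.list(f$pan$params), core = as.list(f$core$params),
      new = as.list(f$new$params), openness = f$openness),
      p, auto_unbox = TRUE, digits = NA)
    pam <- file.path(dir, "pa_matrix.tsv")
    utils::write.table(data.frame(family = rownames(report$pangenome$pa),
                                  report$pangenome$pa + 0L,
                                  check.names = FALSE),
                       pam, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p, pam)
  }
  provPath <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, provPath, auto_unbox = TRUE)
  written <- c(written, provPath)
  invisible(written)
}
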