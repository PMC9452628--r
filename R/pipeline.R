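## End-to-end construct-versus-reference comparison: superposition, geometry
## observables, per-snapshot constraint networks, dilution, stability maps and
## profiles, and reference-minus-construct stability differences, collected
## into a machine-readable report (a named list of plain data.frames that can
## be written as delimited text).

#' Read a run configuration from YAML
#'
#' Keys: \code{ensembles} (list of \code{\{path, construct, run\}}),
#' \code{annotation} (path to a domain-annotation YAML), \code{reference}
#' (construct label, default "0G"), and optional \code{e_cut_grid}
#' (\code{\{from, to, by\}}), \code{contact_cutoff}, \code{alpha},
#' \code{superpose_region}, \code{frames} (subsample count), \code{output_dir}.
#'
#' @param path YAML config path.
#' @return list ready for \code{\link{runComparison}}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ens <- lapply(cfg$ensembles, function(e) {
    if (!file.exists(e$path)) stop("ensemble path does not exist: ", e$path)
    readEnsemble(e$path, construct = e$construct %||% "unknown",
                 runId = e$run %||% "run1")
  })
  grid <- if (!is.null(cfg$e_cut_grid))
    -seq(abs(cfg$e_cut_grid$from), abs(cfg$e_cut_grid$to),
         by = abs(cfg$e_cut_grid$by)) else defaultEcutGrid()
  list(ensembles = ens,
       annotation = readDomainAnnotation(cfg$annotation),
       reference = cfg$reference %||% "0G",
       eCutGrid = grid,
       contactCutoff = cfg$contact_cutoff %||% 4.5,
       alpha = cfg$alpha %||% 0.05,
       superposeRegion = cfg$superpose_region %||% "S6",
       outputDir = cfg$output_dir)
}

## per-chain within-chain profile replicates from a global profile
.profileByChain <- function(profile, rt) {
  lapply(split(seq_len(nrow(rt)), rt$chain), function(rows) {
    v <- profile@Ei[rows]
    names(v) <- rt$resid[rows]
    v[order(rt$resid[rows])]
  })
}

#' Run the construct-versus-reference comparison pipeline
#'
#' Stages: superpose onto the reference region, geometry observables (RMSF,
#' d_z, kink angle, S4-CL contacts and secondary-structure content where the
#' annotation provides the regions), per-snapshot rigidity analysis
#' (dilution, stability maps, ensemble profiles) and per-residue stability
#' differences of each construct against the reference. Deterministic given
#' its inputs.
#'
#' @param ensembles list of \linkS4class{StructureEnsemble}s; several runs per
#'   construct are grouped by construct label.
#' @param annotation a \linkS4class{DomainAnnotation}.
#' @param reference construct label of the reference group (default "0G").
#' @param eCutGrid dilution grid.
#' @param contactCutoff heavy-atom contact cutoff, Angstrom.
#' @param alpha significance level for per-residue tests.
#' @param superposeRegion annotation region used for superposition.
#' @param stages character subset of c("geometry", "rigidity").
#' @param frames optional frame subset applied to every ensemble.
#' @param outputDir optional directory; when given, every report table is
#'   written there as TSV together with a run manifest.
#' @param verbose log stage progress.
#' @return named list of data.frames (the comparison report).
#' @export
runComparison <- function(ensembles, annotation, reference = "0G",
                          eCutGrid = defaultEcutGrid(), contactCutoff = 4.5,
                          alpha = 0.05, superposeRegion = "S6",
                          stages = c("geometry", "rigidity"),
                          frames = NULL, outputDir = NULL, verbose = FALSE) {
  labels <- vapply(ensembles, constructLabel, character(1))
  if (!(reference %in% labels))
    stop("no ensemble carries the reference label '", reference, "'")
  if (length(unique(labels)) < 2L)
    stop("need at least two constructs (reference plus one)")
  say <- function(...) if (verbose) message(sprintf(...))
  sel <- region(annotation, superposeRegion)

  perEns <- lapply(seq_along(ensembles), function(k) {
    e <- ensembles[[k]]
    fr <- if (is.null(frames)) seq_len(nFrames(e)) else
      frames[frames <= nFrames(e)]
    say("[%s/%s] superposing on %s", labels[k], e@runId, superposeRegion)
    e <- superpose(e, sel)
    rt <- residueTable(e)
    out <- list(ensemble = e, frames = fr, rt = rt, label = labels[k],
                run = e@runId)

    if ("geometry" %in% stages) {
      say("[%s/%s] geometry observables", labels[k], e@runId)
      ## per-chain RMSF replicates
      out$rmsf <- do.call(rbind, lapply(unique(rt$chain), function(ch) {
        sub <- e
        keep <- e@atoms$chain == ch
        sub@atoms <- e@atoms[keep, , drop = FALSE]
        sub@coords <- e@coords[keep, , TRUE, drop = FALSE]
        r <- rmsf(sub)
        r$chain <- ch
        r
      }))
      out$dz <- do.call(rbind, lapply(out$frames, function(m) {
        v <- dzDisplacement(getSnapshot(e, m), annotation)
        data.frame(frame = m, chain = names(v), dz = as.numeric(v))
      }))
      haveCL <- !is.null(annotation@regions$CL)
      if (haveCL) {
        s6 <- region(annotation, "S6"); cl <- region(annotation, "CL")
        chains <- unique(rt$chain)
        out$kink <- do.call(rbind, lapply(out$frames, function(m) {
          snap <- getSnapshot(e, m)
          data.frame(frame = m, chain = chains,
                     kink = vapply(chains, function(ch)
                       kinkAngle(snap, tail(sort(s6), 8L),
                                 head(sort(cl), 8L), chain = ch),
                       numeric(1)))
        }))
      }
      if (!is.null(annotation@regions$S4) && haveCL) {
        s4 <- region(annotation, "S4"); cl <- region(annotation, "CL")
        out$contacts <- data.frame(
          frame = out$frames,
          n = vapply(out$frames, function(m)
            countContacts(getSnapshot(e, m), s4, cl, contactCutoff),
            integer(1)))
      }
      if (length(annotation@insertionSite) == 2L) {
        ins <- annotation@insertionSite
        regionRes <- intersect(
          (ins[1] - 2L):(ins[2] + 2L), unique(rt$resid))
        out$ss <- ssContent(e, regionRes, frames = out$frames)
      }
    }

    if ("rigidity" %in% stages) {
      say("[%s/%s] rigidity analysis (%d frames x %d cutoffs)",
          labels[k], e@runId, length(out$frames), length(eCutGrid))
      prof <- ensembleStabilityProfile(e, eCutGrid = eCutGrid,
                                       contactCutoff = contactCutoff,
                                       frames = out$frames)
      out$profile <- prof
      out$profileByChain <- .profileByChain(prof, rt)
    }
    out
  })

  report <- list()
  byLabel <- split(perEns, vapply(perEns, `[[`, character(1), "label"))
  refGroup <- byLabel[[reference]]

  if ("geometry" %in% stages) {
    ## RMSF summary: per construct, per within-chain residue, mean +/- SEM
    ## across chain replicates pooled over runs, plus Welch p vs reference
    rmsfReplicates <- function(group) {
      do.call(rbind, lapply(group, function(g)
        data.frame(resid = g$rmsf$resid, rmsf = g$rmsf$rmsf,
                   rep = paste(g$run, g$rmsf$chain))))
    }
    refR <- rmsfReplicates(refGroup)
    report$rmsf <- do.call(rbind, lapply(names(byLabel), function(lb) {
      rr <- rmsfReplicates(byLabel[[lb]])
      agg <- do.call(rbind, lapply(split(rr, rr$resid), function(d) {
        ref_i <- refR$rmsf[refR$resid == d$resid[1]]
        p <- if (lb == reference) NA_real_ else
          unname(unpairedT(ref_i, d$rmsf)["p"])
        data.frame(construct = lb, resid = d$resid[1],
                   rmsf = mean(d$rmsf),
                   sem = sd(d$rmsf) / sqrt(nrow(d)),
                   n = nrow(d), p = p)
      }))
      agg[order(agg$resid), ]
    }))
    rownames(report$rmsf) <- NULL

    report$dz <- do.call(rbind, lapply(names(byLabel), function(lb) {
      v <- unlist(lapply(byLabel[[lb]], function(g) g$dz$dz))
      runMeans <- vapply(byLabel[[lb]], function(g) mean(g$dz$dz), numeric(1))
      data.frame(construct = lb, mean = mean(runMeans),
                 sem = if (length(runMeans) > 1L)
                   sd(runMeans) / sqrt(length(runMeans)) else NA_real_,
                 peak = max(v), n = length(v))
    }))

    if (!is.null(perEns[[1]]$kink))
      report$kink <- do.call(rbind, lapply(names(byLabel), function(lb) {
        v <- unlist(lapply(byLabel[[lb]], function(g) g$kink$kink))
        data.frame(construct = lb, mean = mean(v), sd = sd(v),
                   peak = max(v), n = length(v))
      }))

    if (!is.null(perEns[[1]]$contacts))
      report$contacts <- do.call(rbind, lapply(names(byLabel), function(lb) {
        v <- unlist(lapply(byLabel[[lb]], function(g) g$contacts$n))
        q <- quantile(v, c(0.25, 0.5, 0.75))
        data.frame(construct = lb, mean = mean(v), q25 = q[1], median = q[2],
                   q75 = q[3], n = length(v))
      }))

    if (!is.null(perEns[[1]]$ss))
      report$ss <- do.call(rbind, lapply(names(byLabel), function(lb) {
        m <- vapply(byLabel[[lb]], function(g) g$ss, numeric(3))
        data.frame(construct = lb, fraction = mean(m["fraction", ]),
                   sem = mean(m["sem", ]), n = sum(m["n", ]))
      }))
  }

  if ("rigidity" %in% stages) {
    refReps <- unlist(lapply(refGroup, function(g) g$profileByChain),
                      recursive = FALSE)
    deltas <- list()
    for (lb in setdiff(names(byLabel), reference)) {
      conReps <- unlist(lapply(byLabel[[lb]], function(g) g$profileByChain),
                        recursive = FALSE)
      deltas[[lb]] <- deltaStability(refReps, conReps, alpha = alpha)
    }
    report$deltaStability <- do.call(rbind, lapply(names(deltas), function(lb) {
      d <- deltas[[lb]]
      data.frame(construct = lb, resid = d@residue, dE = d@dE,
                 dEReported = d@dEReported, p = d@p,
                 significant = d@significant,
                 n = length(refReps) + length(unlist(lapply(byLabel[[lb]],
                   function(g) g$profileByChain), recursive = FALSE)))
    }))
    report$deltaObjects <- deltas
    ## region averages over every annotated region
    report$regionDelta <- do.call(rbind, lapply(names(deltas), function(lb) {
      do.call(rbind, lapply(names(annotation@regions), function(rg) {
        res <- intersect(annotation@regions[[rg]], deltas[[lb]]@residue)
        if (!length(res)) return(NULL)
        v <- regionAverage(deltas[[lb]], res)
        data.frame(construct = lb, region = rg, mean = v["mean"],
                   sd = v["sd"], n = v["n"])
      }))
    }))
    if (!is.null(report$regionDelta)) rownames(report$regionDelta) <- NULL
  }

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      if (!is.data.frame(report[[nm]])) next
      write.table(report[[nm]], file.path(outputDir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- c(
      sprintf("constructs = %s", paste(unique(labels), collapse = ",")),
      sprintf("reference = %s", reference),
      sprintf("e_cut_grid = %g..%g by %g", max(eCutGrid), min(eCutGrid),
              if (length(eCutGrid) > 1) abs(diff(eCutGrid[1:2])) else 0),
      sprintf("contact_cutoff = %g", contactCutoff),
      sprintf("alpha = %g", alpha),
      sprintf("superpose_region = %s", superposeRegion),
      sprintf("package = cnaflex %s",
              as.character(utils::packageVersion("cnaflex"))))
    writeLines(manifest, file.path(outputDir, "manifest.txt"))
  }
  report
}
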