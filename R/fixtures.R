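#' Packaged reference fixtures
#'
#' Plain-text fixtures transcribed from the published cross-disease fibrotic
#' signature study that this workflow re-implements:
#'
#' \describe{
#'   \item{`table1_samples`}{annotation of the 44 paired intestinal biopsies
#'     (22 patients, one terminal-ileum and one sigmoid sample each; 7 CD,
#'     6 UC, 9 control individuals). Control samples are labeled `CI`.}
#'   \item{`table2_fibsig`}{the 241-gene cross-disease fibrotic signature
#'     (FIBSig), the intersection of a Crohn's-disease pool and a pool from
#'     four other fibrotic disorders.}
#'   \item{`table3_m1`}{the 112 genes of the M1 co-expression module found
#'     within FIBSig in the paired-biopsy cohort.}
#'   \item{`hub21`}{the 21 high-degree hub genes of the M1 interaction
#'     subnetwork.}
#'   \item{`shared20`}{the 20 FIBSig genes co-expressed in both the terminal
#'     ileum and the sigmoid.}
#'   \item{`cd7`}{the 7 genes differentially expressed in all nine
#'     Crohn's-disease cohorts.}
#' }
#'
#' @param name one of `"table1_samples"`, `"table2_fibsig"`, `"table3_m1"`,
#'   `"hub21"`, `"shared20"`, `"cd7"`.
#' @return a `sample_annotation` for `table1_samples`, otherwise a
#'   `gene_set`.
#' @examples
#' length(load_fixture("table2_fibsig"))
#' @export
load_fixture <- function(name = c("table1_samples", "table2_fibsig",
                                  "table3_m1", "hub21", "shared20", "cd7")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      if (name == "table1_samples") "table1_samples.tsv"
                      else paste0(name, ".txt"),
                      package = "fibsig", mustWork = TRUE)
  if (name == "table1_samples") {
    read_sample_annotation(path)
  } else {
    read_gene_list(path, name = name)
  }
}
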