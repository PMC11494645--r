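# shared fixtures: records and mapped reactions built in code

mk_record <- function(smiles, id = "r1", ...) {
  reaction_record(id, smiles, ...)
}

mk_mapped <- function(smiles, id = "r1", ...) {
  cu <- curate_structures(reaction_record(id, smiles, ...))
  stopifnot(inherits(cu, "curated_reaction"))
  as_mapped_reaction(cu)
}

# the worked mapped examples used across center/classification tests
DENITROSATION_RXN <- "[CH3:1][N:2]([CH3:3])[N:4]=[O:5]>>[CH3:1][NH:2][CH3:3].[NH:4]=[O:5]"
HYDRAZINE_RXN <- "[CH3:1][N:2]([CH3:3])[N:4]=[O:5]>>[CH3:1][N:2]([CH3:3])[NH2:4].[OH2:5]"
SPECTATOR_RXN <- paste0(
  "[O:9]=[N:8][N:7]([CH3:6])[CH2:4][CH2:3][OH:2].[CH3:10][C:11](=[O:12])Cl>>",
  "[O:9]=[N:8][N:7]([CH3:6])[CH2:4][CH2:3][O:2][C:11]([CH3:10])=[O:12].Cl")
IDENTITY_RXN <- "[CH3:1][N:2]([CH3:3])[N:4]=[O:5]>>[CH3:1][N:2]([CH3:3])[N:4]=[O:5]"

# a moderate synthetic dataset reused by pipeline-level unit tests
small_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- generate_dataset(synthetic_dataset_spec(
        n_per_pair = 2, n_multistep = 3, n_unparseable = 3, n_unbalanced = 3,
        n_spectator = 4, n_duplicates = 5, seed = 7))
    }
    memo
  }
})
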