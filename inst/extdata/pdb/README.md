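# Deposited entry drop-in directory

The comparative checks and the worked examples operate on the deposited
TrmI crystal structures:

    2B25 1I9G 2PWY 1O54 2YVL 3LHD 3LGA 3MB5

Coordinate files are not redistributed with the package. To run the
comparative test blocks and the full acceptance analysis, download each
entry from the PDB (https://files.rcsb.org/download/<ID>.pdb) and place it
here as `<id>.pdb` (lowercase) or `<id>.cif` before installing, e.g.

    inst/extdata/pdb/2pwy.pdb

Everything else in the package (unit tests, property suites, synthetic
fixtures, the acceptance script defaults) runs without these files.
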