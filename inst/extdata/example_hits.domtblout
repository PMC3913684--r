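#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord
# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target
#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------
Rep_1                PF01446.12   230 g001                 -            166   1.2e-12   45.3   0.1   1   1   2.1e-14   1.2e-12   44.8   0.1     3   160     5   162     2   165 0.92 Replication protein
HTH_23               PF13384.9     55 g001                 -            166     3e-03   12.1   0.0   1   1   5.2e-05     3e-03   11.5   0.0     1    50    10    60     8    62 0.77 Homeodomain-like domain
Rep_3                PF01051.16   260 g002                 -            210   5.1e-07   28.9   0.0   1   1   8.8e-09   5.1e-07   28.1   0.0    10   200    15   205    12   208 0.88 Initiator Replication protein
Phage_integrase      PF00589.22   173 g003                 -            150   2.2e-09   35.0   0.0   1   1   4.0e-11   2.2e-09   34.2   0.0     1   170     2   148     1   150 0.90 Site-specific recombinase
#
# Program:         hmmscan
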