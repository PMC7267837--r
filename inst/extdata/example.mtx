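%%MatrixMarket matrix coordinate integer general
% toy example: 6 genes (rows) x 4 cells (columns)
6 4 9
1 1 4
2 1 1
3 2 7
4 2 2
1 3 5
5 3 3
6 4 1
2 4 6
4 4 8
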