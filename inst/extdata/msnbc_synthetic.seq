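% synthetic sessions in the UCI MSNBC sequence dialect (not real data)
% one legend line naming the categories, then 1-based index sequences
frontpage news tech local sports
1 1 2
2
3 4 4 5
1 2 3 4 5
5 5
2 1
4
3 3 3
1 5 1
2 4 2 4
5 1 2
3
2 2
4 5
1 1 1 1
5 4 3 2 1
2 3
4 4
1 3 5
5 2 4 1 3
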