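# pioneerscan bundled motif library.
# Synthetic count matrices (scale 100) encoding the consensus patterns of the
# motif families used by the analyses; rows are A, C, G, T in order. These are
# test fixtures, not curated-database matrices.
>GATA
A 45  2 90  2 92 48
C  3  2  3  2  2  4
G  4 92  3  2  3 44
T 48  4  4 94  3  4
>MEF2
A  3  2 80 45 48 46 44  2 75  3
C 90  3  4  3  2  2  3  3  5  4
G  3  3  4  2  2  2  3  2 15 90
T  4 92 12 50 48 50 50 93  5  3
>NFY
A  4  4 85 85  3
C 90 90  5  5  4
G  3  3  5  5  3
T  3  3  5  5 90
>SOX
A 80 85  4 85 85  5
C  6  5 88  4  4  4
G  7  5  4  5  4  4
T  7  5  4  6  7 87
>HAND
A  4  85  3  4  3  4
C  88  4  4 88  3  4
G  4   4  3  4  3 88
T  4   7 90  4 91  4
>CTCF
A  5  5  5  5  5 35  5  5  5  5 30  5
C 80 80  5 80  5 30 80  5  5 80 30 80
G  5  5 85  5 85 30  5 85 85  5 35  5
T 10 10  5 10  5  5 10  5  5 10  5 10
>SP1
A  5  5  5  5  8  5  5  5 10
C  5  5  5  5  8 80  5  5 10
G 85 85 85 85 76 10 85 85 70
T  5  5  5  5  8  5  5  5 10
>RARA
A 85  5  5  5  8 80
C  5  5  5  5  8  5
G  5 85 85  5 76  5
T  5  5  5 85  8 10
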