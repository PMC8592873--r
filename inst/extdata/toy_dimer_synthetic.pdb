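ATOM      1  N   GLY A   1       2.450   1.100   0.300  1.00  0.00           N  
ATOM      2  CA  GLY A   1       1.850   0.500   0.300  1.00  0.00           C  
ATOM      3  C   GLY A   1       1.850   1.100  -0.300  1.00  0.00           C  
ATOM      4  O   GLY A   1       2.450   0.500  -0.300  1.00  0.00           O  
ATOM      5  N   GLY A   2       4.600   0.300   0.300  1.00  0.00           N  
ATOM      6  CA  GLY A   2       4.000  -0.300   0.300  1.00  0.00           C  
ATOM      7  C   GLY A   2       4.000   0.300  -0.300  1.00  0.00           C  
ATOM      8  O   GLY A   2       4.600  -0.300  -0.300  1.00  0.00           O  
ATOM      9  N   GLY A   3       6.750   1.100   0.300  1.00  0.00           N  
ATOM     10  CA  GLY A   3       6.150   0.500   0.300  1.00  0.00           C  
ATOM     11  C   GLY A   3       6.150   1.100  -0.300  1.00  0.00           C  
ATOM     12  O   GLY A   3       6.750   0.500  -0.300  1.00  0.00           O  
ATOM     13  N   GLY A   4       8.900   0.300   0.300  1.00  0.00           N  
ATOM     14  CA  GLY A   4       8.300  -0.300   0.300  1.00  0.00           C  
ATOM     15  C   GLY A   4       8.300   0.300  -0.300  1.00  0.00           C  
ATOM     16  O   GLY A   4       8.900  -0.300  -0.300  1.00  0.00           O  
ATOM     17  N   GLY A   5      11.050   1.100   0.300  1.00  0.00           N  
ATOM     18  CA  GLY A   5      10.450   0.500   0.300  1.00  0.00           C  
ATOM     19  C   GLY A   5      10.450   1.100  -0.300  1.00  0.00           C  
ATOM     20  O   GLY A   5      11.050   0.500  -0.300  1.00  0.00           O  
ATOM     21  N   GLY A   6      13.200   0.300   0.300  1.00  0.00           N  
ATOM     22  CA  GLY A   6      12.600  -0.300   0.300  1.00  0.00           C  
ATOM     23  C   GLY A   6      12.600   0.300  -0.300  1.00  0.00           C  
ATOM     24  O   GLY A   6      13.200  -0.300  -0.300  1.00  0.00           O  
ATOM     25  N   GLY A   7      15.350   1.100   0.300  1.00  0.00           N  
ATOM     26  CA  GLY A   7      14.750   0.500   0.300  1.00  0.00           C  
ATOM     27  C   GLY A   7      14.750   1.100  -0.300  1.00  0.00           C  
ATOM     28  O   GLY A   7      15.350   0.500  -0.300  1.00  0.00           O  
ATOM     29  N   GLY A   8      17.500   0.300   0.300  1.00  0.00           N  
ATOM     30  CA  GLY A   8      16.900  -0.300   0.300  1.00  0.00           C  
ATOM     31  C   GLY A   8      16.900   0.300  -0.300  1.00  0.00           C  
ATOM     32  O   GLY A   8      17.500  -0.300  -0.300  1.00  0.00           O  
ATOM     33  N   GLY A   9      19.650   1.100   0.300  1.00  0.00           N  
ATOM     34  CA  GLY A   9      19.050   0.500   0.300  1.00  0.00           C  
ATOM     35  C   GLY A   9      19.050   1.100  -0.300  1.00  0.00           C  
ATOM     36  O   GLY A   9      19.650   0.500  -0.300  1.00  0.00           O  
ATOM     37  N   GLY A  10      21.800   0.300   0.300  1.00  0.00           N  
ATOM     38  CA  GLY A  10      21.200  -0.300   0.300  1.00  0.00           C  
ATOM     39  C   GLY A  10      21.200   0.300  -0.300  1.00  0.00           C  
ATOM     40  O   GLY A  10      21.800  -0.300  -0.300  1.00  0.00           O  
ATOM     41  N   GLY A  11      23.950   1.100   0.300  1.00  0.00           N  
ATOM     42  CA  GLY A  11      23.350   0.500   0.300  1.00  0.00           C  
ATOM     43  C   GLY A  11      23.350   1.100  -0.300  1.00  0.00           C  
ATOM     44  O   GLY A  11      23.950   0.500  -0.300  1.00  0.00           O  
ATOM     45  N   GLY A  12      26.100   0.300   0.300  1.00  0.00           N  
ATOM     46  CA  GLY A  12      25.500  -0.300   0.300  1.00  0.00           C  
ATOM     47  C   GLY A  12      25.500   0.300  -0.300  1.00  0.00           C  
ATOM     48  O   GLY A  12      26.100  -0.300  -0.300  1.00  0.00           O  
ATOM     49  N   GLY B   1      16.150 -12.600   3.700  1.00  0.00           N  
ATOM     50  CA  GLY B   1      15.550 -13.200   3.700  1.00  0.00           C  
ATOM     51  C   GLY B   1      15.550 -12.600   3.100  1.00  0.00           C  
ATOM     52  O   GLY B   1      16.150 -13.200   3.100  1.00  0.00           O  
ATOM     53  N   GLY B   2      15.350 -10.450   3.700  1.00  0.00           N  
ATOM     54  CA  GLY B   2      14.750 -11.050   3.700  1.00  0.00           C  
ATOM     55  C   GLY B   2      14.750 -10.450   3.100  1.00  0.00           C  
ATOM     56  O   GLY B   2      15.350 -11.050   3.100  1.00  0.00           O  
ATOM     57  N   GLY B   3      16.150  -8.300   3.700  1.00  0.00           N  
ATOM     58  CA  GLY B   3      15.550  -8.900   3.700  1.00  0.00           C  
ATOM     59  C   GLY B   3      15.550  -8.300   3.100  1.00  0.00           C  
ATOM     60  O   GLY B   3      16.150  -8.900   3.100  1.00  0.00           O  
ATOM     61  N   GLY B   4      15.350  -6.150   3.700  1.00  0.00           N  
ATOM     62  CA  GLY B   4      14.750  -6.750   3.700  1.00  0.00           C  
ATOM     63  C   GLY B   4      14.750  -6.150   3.100  1.00  0.00           C  
ATOM     64  O   GLY B   4      15.350  -6.750   3.100  1.00  0.00           O  
ATOM     65  N   GLY B   5      16.150  -4.000   3.700  1.00  0.00           N  
ATOM     66  CA  GLY B   5      15.550  -4.600   3.700  1.00  0.00           C  
ATOM     67  C   GLY B   5      15.550  -4.000   3.100  1.00  0.00           C  
ATOM     68  O   GLY B   5      16.150  -4.600   3.100  1.00  0.00           O  
ATOM     69  N   GLY B   6      15.350  -1.850   3.700  1.00  0.00           N  
ATOM     70  CA  GLY B   6      14.750  -2.450   3.700  1.00  0.00           C  
ATOM     71  C   GLY B   6      14.750  -1.850   3.100  1.00  0.00           C  
ATOM     72  O   GLY B   6      15.350  -2.450   3.100  1.00  0.00           O  
ATOM     73  N   GLY B   7      16.150   0.300   3.700  1.00  0.00           N  
ATOM     74  CA  GLY B   7      15.550  -0.300   3.700  1.00  0.00           C  
ATOM     75  C   GLY B   7      15.550   0.300   3.100  1.00  0.00           C  
ATOM     76  O   GLY B   7      16.150  -0.300   3.100  1.00  0.00           O  
ATOM     77  N   GLY B   8      15.350   2.450   3.700  1.00  0.00           N  
ATOM     78  CA  GLY B   8      14.750   1.850   3.700  1.00  0.00           C  
ATOM     79  C   GLY B   8      14.750   2.450   3.100  1.00  0.00           C  
ATOM     80  O   GLY B   8      15.350   1.850   3.100  1.00  0.00           O  
ATOM     81  N   GLY B   9      16.150   4.600   3.700  1.00  0.00           N  
ATOM     82  CA  GLY B   9      15.550   4.000   3.700  1.00  0.00           C  
ATOM     83  C   GLY B   9      15.550   4.600   3.100  1.00  0.00           C  
ATOM     84  O   GLY B   9      16.150   4.000   3.100  1.00  0.00           O  
ATOM     85  N   GLY B  10      15.350   6.750   3.700  1.00  0.00           N  
ATOM     86  CA  GLY B  10      14.750   6.150   3.700  1.00  0.00           C  
ATOM     87  C   GLY B  10      14.750   6.750   3.100  1.00  0.00           C  
ATOM     88  O   GLY B  10      15.350   6.150   3.100  1.00  0.00           O  
ATOM     89  N   GLY B  11      16.150   8.900   3.700  1.00  0.00           N  
ATOM     90  CA  GLY B  11      15.550   8.300   3.700  1.00  0.00           C  
ATOM     91  C   GLY B  11      15.550   8.900   3.100  1.00  0.00           C  
ATOM     92  O   GLY B  11      16.150   8.300   3.100  1.00  0.00           O  
ATOM     93  N   GLY B  12      15.350  11.050   3.700  1.00  0.00           N  
ATOM     94  CA  GLY B  12      14.750  10.450   3.700  1.00  0.00           C  
ATOM     95  C   GLY B  12      14.750  11.050   3.100  1.00  0.00           C  
ATOM     96  O   GLY B  12      15.350  10.450   3.100  1.00  0.00           O  
END   
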