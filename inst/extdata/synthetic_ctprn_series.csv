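construct_id,denaturant_M,signal
CTPR2,0,0.0282253390052854
CTPR2,0.428571428571429,-0.009599127698523
CTPR2,0.857142857142857,0.0108774667247072
CTPR2,1.28571428571429,0.0208213079632993
CTPR2,1.71428571428571,0.0307905219682106
CTPR2,2.14285714285714,0.0938485310800446
CTPR2,2.57142857142857,0.455788491666653
CTPR2,3,0.845919115688024
CTPR2,3.42857142857143,1.01251179179783
CTPR2,3.85714285714286,0.992075210792444
CTPR2,4.28571428571429,1.02341449977408
CTPR2,4.71428571428571,1.04401469682753
CTPR2,5.14285714285714,0.970805708572683
CTPR2,5.57142857142857,0.993123522254975
CTPR2,6,0.996085606976514
CTPR2dA,0,0.0152623065398566
CTPR2dA,0.428571428571429,0.000330527903492202
CTPR2dA,0.857142857142857,-0.0344263005014234
CTPR2dA,1.28571428571429,0.0229221575022569
CTPR2dA,1.71428571428571,0.290541329230082
CTPR2dA,2.14285714285714,0.627103305267198
CTPR2dA,2.57142857142857,0.853160455923651
CTPR2dA,3,0.967015155106585
CTPR2dA,3.42857142857143,1.01503054464538
CTPR2dA,3.85714285714286,1.03387127250512
CTPR2dA,4.28571428571429,0.988918293244154
CTPR2dA,4.71428571428571,0.992935153176929
CTPR2dA,5.14285714285714,0.963045377735793
CTPR2dA,5.57142857142857,1.00761639581923
CTPR2dA,6,0.985668098373077
CTPR2dS,0,0.0111469561703264
CTPR2dS,0.428571428571429,0.0182486421808785
CTPR2dS,0.857142857142857,0.0313615814770103
CTPR2dS,1.28571428571429,0.0231195367009378
CTPR2dS,1.71428571428571,0.141087541880049
CTPR2dS,2.14285714285714,0.369274013553723
CTPR2dS,2.57142857142857,0.739484924485022
CTPR2dS,3,0.914587760449885
CTPR2dS,3.42857142857143,0.934055889516749
CTPR2dS,3.85714285714286,0.995690360881632
CTPR2dS,4.28571428571429,1.00237189781702
CTPR2dS,4.71428571428571,0.991998441007941
CTPR2dS,5.14285714285714,1.01471816416021
CTPR2dS,5.57142857142857,0.985157370840298
CTPR2dS,6,0.972389409871924
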